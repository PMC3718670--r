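#' Convert a Phred score to a correctness probability
#'
#' A Phred score Q encodes an error probability of `10^(-Q/10)`; the
#' probability that the read placement (mapping quality) or base call (base
#' quality) is correct is therefore `1 - 10^(-Q/10)`.
#'
#' @param phred Numeric vector of non-negative Phred scores.
#' @return Numeric vector of correctness probabilities in `[0, 1)`.
#' @examples
#' phred_to_prob(c(0, 10, 20, 30))
#' @export
phred_to_prob <- function(phred) {
  if (length(phred) && (any(!is.finite(phred)) | any(phred < 0)))
    stop("Phred scores must be finite and non-negative")
  1 - 10^(-phred / 10)
}

#' Filtering thresholds for pileup reduction and SNV reporting
#'
#' @param mq_min Minimum Phred mapping quality a read must have to be used.
#' @param bq_min Minimum Phred base quality a base call must have to be used.
#' @param mvc Minimum valid coverage: the least number of retained reads a
#'   site needs for an ab/bb call to be reported as an SNV. A moderate MVC of
#'   15--25% of the mean sequencing depth is a good starting point (roughly
#'   2--5 at 10X, 6--9 at 40X).
#' @return A `filter_config` object.
#' @export
filter_config <- function(mq_min = 50L, bq_min = 20L, mvc = 4L) {
  mq_min <- as.integer(mq_min); bq_min <- as.integer(bq_min); mvc <- as.integer(mvc)
  stopifnot(length(mq_min) == 1L, length(bq_min) == 1L, length(mvc) == 1L)
  if (anyNA(c(mq_min, bq_min, mvc)) || mq_min < 0L || bq_min < 0L || mvc < 0L)
    stop("mq_min, bq_min and mvc must be non-negative integers")
  structure(list(mq_min = mq_min, bq_min = bq_min, mvc = mvc),
            class = "filter_config")
}

# Decode one pileup base-call string together with its quality strings into
# per-read (base, base_qual, map_qual) triples.  Grammar handled:
#   '.' / ','      read base equals the reference base
#   ACGTNacgtn     literal base (case folded)
#   '^X'           read start; X is the read's mapping quality char, consumed
#   '$'            read end marker, consumed
#   '+n<seq>'/'-n<seq>'  indel run, consumed and discarded
#   '*'            deletion placeholder: consumes a quality char, read dropped
# 'N' reads are decoded here and dropped, matching the '*' treatment.
decode_base_string <- function(bases, bquals, mquals, ref, default_mq,
                               qual_offset, line_num = NA_integer_) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  n_q <- nchar(bquals)
  has_mq <- !is.na(mquals)
  base_out <- character(n_q)
  keep <- logical(n_q)
  i <- 1L; j <- 0L
  digits <- as.character(0:9)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L           # '^' plus the mapping-quality char of the new read
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      k <- i + 1L
      while (k <= n && chars[k] %in% digits) k <- k + 1L
      if (k == i + 1L)
        stop(sprintf("malformed indel run in pileup line %s", line_num))
      len <- as.integer(paste0(chars[(i + 1L):(k - 1L)], collapse = ""))
      i <- k + len
    } else {
      j <- j + 1L
      if (j > n_q)
        stop(sprintf("base/quality string length mismatch in pileup line %s", line_num))
      if (ch == "." || ch == ",") {
        base_out[j] <- ref; keep[j] <- TRUE
      } else if (ch %in% c("A", "C", "G", "T", "a", "c", "g", "t")) {
        base_out[j] <- toupper(ch); keep[j] <- TRUE
      } else if (ch == "*" || ch == "N" || ch == "n") {
        keep[j] <- FALSE
      } else {
        stop(sprintf("unrecognized pileup base symbol '%s' in line %s", ch, line_num))
      }
      i <- i + 1L
    }
  }
  if (j != n_q)
    stop(sprintf("base/quality string length mismatch in pileup line %s", line_num))
  if (has_mq && nchar(mquals) != j)
    stop(sprintf("base/mapping-quality length mismatch in pileup line %s", line_num))
  bq <- utf8ToInt(bquals) - qual_offset
  mq <- if (has_mq) utf8ToInt(mquals) - qual_offset else rep(default_mq, j)
  keep <- keep
  data.frame(base = base_out[keep], base_qual = as.integer(bq[keep]),
             map_qual = as.integer(mq[keep]), stringsAsFactors = FALSE)
}

#' Parse a single pileup line into a raw per-read record
#'
#' Supports the 6-column SAMtools mpileup layout (chrom, pos, ref, depth,
#' bases, base qualities) with an optional 7th per-read mapping-quality
#' column. The Maq pileup dialect is mapped onto the same record: identical
#' column order, with a possible `@` prefix on the base column. When the
#' mapping-quality column is absent every read is assigned `default_mq`.
#'
#' @param line A single tab-separated pileup row.
#' @param dialect `"samtools"` (default) or `"maq"`.
#' @param default_mq Phred mapping quality assumed when no per-read mapping
#'   qualities are present (default 30).
#' @param qual_offset ASCII offset of the quality encoding: 33 (modern
#'   standard, default) or 64 for legacy Illumina data.
#' @param line_num Optional line number used in error messages.
#' @return A `pileup_record`: list with `chrom`, `pos`, `ref` and a data
#'   frame `reads` of (base, base_qual, map_qual).
#' @export
parse_pileup_line <- function(line, dialect = c("samtools", "maq"),
                              default_mq = 30L, qual_offset = 33L,
                              line_num = NA_integer_) {
  dialect <- match.arg(dialect)
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 4L)
    stop(sprintf("pileup line %s: expected at least 4 tab-separated columns, got %d",
                 line_num, length(f)))
  pos <- suppressWarnings(as.integer(f[2]))
  depth <- suppressWarnings(as.integer(f[4]))
  if (is.na(pos) || is.na(depth))
    stop(sprintf("pileup line %s: non-numeric position or depth", line_num))
  ref <- toupper(f[3])
  bases <- if (length(f) >= 5L) f[5] else ""
  bquals <- if (length(f) >= 6L) f[6] else ""
  mquals <- if (length(f) >= 7L && nzchar(f[7])) f[7] else NA_character_
  if (dialect == "maq") bases <- sub("^@", "", bases)
  if (depth == 0L || !nzchar(bases) || bases == "*") {
    reads <- data.frame(base = character(0), base_qual = integer(0),
                        map_qual = integer(0), stringsAsFactors = FALSE)
  } else {
    reads <- decode_base_string(bases, bquals, mquals, ref,
                                default_mq, qual_offset, line_num)
  }
  structure(list(chrom = f[1], pos = pos, ref = ref, reads = reads),
            class = "pileup_record")
}

#' Reduce a raw pileup record to the model's per-site observation
#'
#' Applies the read-level filters and the top-2 allele rule: (1) reads below
#' `mq_min`/`bq_min` are dropped; (2) among survivors only the two most
#' frequent nucleotides are retained -- rarer third alleles are treated as
#' sequencing errors and removed (ties broken by count, then reference
#' status, then alphabet); (3) the remaining reads define the coverage
#' `L`, the reference-match count `P`, and per-read correctness
#' probabilities `r` (mapping) and `q` (base call).
#'
#' @param record A `pileup_record`.
#' @param filt A [filter_config()].
#' @return A list with `chrom`, `pos`, `ref`, `alt` (most frequent retained
#'   non-reference allele, `NA` if none), `L`, `P`, and vectors `match`,
#'   `r`, `q`; or `NULL` when no read survives or the reference base is `N`.
#' @export
reduce_to_observation <- function(record, filt = filter_config()) {
  if (!record$ref %in% c("A", "C", "G", "T")) return(NULL)
  rd <- record$reads
  rd <- rd[rd$map_qual >= filt$mq_min & rd$base_qual >= filt$bq_min, , drop = FALSE]
  if (!nrow(rd)) return(NULL)
  cnt <- table(rd$base)
  alleles <- names(cnt)
  ord <- order(-as.integer(cnt), alleles != record$ref, alleles)
  top <- alleles[head(ord, 2L)]
  rd <- rd[rd$base %in% top, , drop = FALSE]
  match <- rd$base == record$ref
  alt_cand <- setdiff(top, record$ref)
  list(chrom = record$chrom, pos = record$pos, ref = record$ref,
       alt = if (length(alt_cand)) alt_cand[1] else NA_character_,
       L = nrow(rd), P = sum(match), match = match,
       r = phred_to_prob(rd$map_qual), q = phred_to_prob(rd$base_qual))
}

#' Read a pileup file into an ordered observation set
#'
#' Parses a (optionally gzipped) pileup file, reduces every line exactly as
#' [reduce_to_observation()] does, drops sites with no surviving read, and
#' returns the remainder in file order -- the order that defines the Markov
#' chain. Chains break at chromosome boundaries; consecutive surviving sites
#' are adjacent in the chain regardless of genomic gaps. Input must be
#' position-sorted within each chromosome, each chromosome one contiguous
#' block.
#'
#' Lines containing only plain base symbols are decoded in bulk; lines using
#' the extended grammar (`^`, `$`, indels, `*`) fall back to
#' [parse_pileup_line()].
#'
#' @inheritParams parse_pileup_line
#' @param path Path to a SAMtools/Maq pileup file (plain text or gzip).
#' @param filt A [filter_config()]; `mvc` is not applied here (it gates
#'   reporting, not model input).
#' @return An [snv_obs] observation set.
#' @export
read_pileup <- function(path, filt = filter_config(),
                        dialect = c("samtools", "maq"),
                        default_mq = 30L, qual_offset = 33L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pileup file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty pileup file: ", path)

  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 4L) stop("pileup file ", path, ": fewer than 4 columns")
  chrom <- f[[1]]
  pos <- suppressWarnings(as.integer(f[[2]]))
  ref <- toupper(f[[3]])
  depth <- suppressWarnings(as.integer(f[[4]]))
  bad <- which(is.na(pos) | is.na(depth))
  if (length(bad))
    stop(sprintf("pileup line %d: non-numeric position or depth", bad[1]))
  bases <- if (length(f) >= 5L) f[[5]] else rep(NA_character_, length(lines))
  bquals <- if (length(f) >= 6L) f[[6]] else rep(NA_character_, length(lines))
  mquals <- if (length(f) >= 7L) f[[7]] else rep(NA_character_, length(lines))
  mquals[!is.na(mquals) & !nzchar(mquals)] <- NA_character_
  if (dialect == "maq") bases <- sub("^@", "", bases)

  empty <- depth == 0L | is.na(bases) | !nzchar(bases) | bases == "*"
  plain <- !empty & !grepl("[^.,ACGTNacgtn]", bases)

  # Bulk path: one long (line, base, bq, mq) table for all plain lines.
  mk_long <- function(idx, base_chr, bq_int, mq_int) {
    data.table::data.table(line = idx, base = base_chr, base_qual = bq_int,
                           map_qual = mq_int)
  }
  long <- list()
  pi_ <- which(plain)
  if (length(pi_)) {
    nb <- nchar(bases[pi_])
    if (any(nb != nchar(bquals[pi_])))
      stop(sprintf("base/quality string length mismatch in pileup line %d",
                   pi_[which(nb != nchar(bquals[pi_]))[1]]))
    has_mq <- !is.na(mquals[pi_])
    if (any(has_mq & nchar(mquals[pi_]) != nb))
      stop(sprintf("base/mapping-quality length mismatch in pileup line %d",
                   pi_[which(has_mq & nchar(mquals[pi_]) != nb)[1]]))
    idx <- rep(pi_, nb)
    chars <- strsplit(paste0(bases[pi_], collapse = ""), "", fixed = TRUE)[[1]]
    bq <- as.integer(charToRaw(paste0(bquals[pi_], collapse = ""))) - qual_offset
    mq <- integer(length(idx))
    mq_str <- mquals[pi_]
    mq_str[!has_mq] <- strrep(intToUtf8(default_mq + qual_offset), nb[!has_mq])
    mq <- as.integer(charToRaw(paste0(mq_str, collapse = ""))) - qual_offset
    is_ref <- chars == "." | chars == ","
    base_chr <- toupper(chars)
    base_chr[is_ref] <- ref[idx][is_ref]
    ok <- base_chr %in% c("A", "C", "G", "T")
    long[[1L]] <- mk_long(idx[ok], base_chr[ok], bq[ok], mq[ok])
  }
  ci <- which(!plain & !empty)
  if (length(ci)) {
    cplx <- lapply(ci, function(k) {
      rd <- decode_base_string(bases[k], bquals[k], mquals[k], ref[k],
                               default_mq, qual_offset, line_num = k)
      if (nrow(rd)) mk_long(rep(k, nrow(rd)), rd$base, rd$base_qual, rd$map_qual)
    })
    long <- c(long, cplx[!vapply(cplx, is.null, logical(1))])
  }
  if (!length(long)) stop("no site in ", path, " survives the filters")
  DT <- data.table::rbindlist(long)
  data.table::setorder(DT, line)
  DT <- DT[ref[DT$line] %in% c("A", "C", "G", "T")]
  DT <- DT[DT$base_qual >= filt$bq_min & DT$map_qual >= filt$mq_min]
  if (!nrow(DT)) stop("no site in ", path, " survives the filters")

  # Top-2 allele rule, vectorized; tie-break mirrors reduce_to_observation.
  DT[, `:=`(rid = .I, is_ref = base == ref[line])]
  cnt <- DT[, .N, by = c("line", "base", "is_ref")]
  cnt[, notref := !is_ref]
  data.table::setorder(cnt, line, -N, notref, base)
  cnt[, rank := seq_len(.N), by = "line"]
  top2 <- cnt[cnt$rank <= 2L]
  DT <- DT[top2[, c("line", "base")], on = c("line", "base"), nomatch = NULL]
  data.table::setorder(DT, rid)

  alt <- top2[top2$notref == TRUE,
              list(alt = base[which.max(N)]), by = "line"]
  sites <- DT[, list(L = .N, P = sum(is_ref)), by = "line"]
  sites <- merge(sites, alt, by = "line", all.x = TRUE, sort = TRUE)
  data.table::setorder(sites, line)

  keep_lines <- sites$line
  out_sites <- data.frame(
    chrom = chrom[keep_lines], pos = pos[keep_lines], ref = ref[keep_lines],
    alt = sites$alt, L = as.integer(sites$L), P = as.integer(sites$P),
    stringsAsFactors = FALSE)
  blocks <- rle(out_sites$chrom)$values
  if (anyDuplicated(blocks))
    stop("pileup file is not sorted: chromosome blocks are not contiguous")
  for (ch in blocks) {
    p <- out_sites$pos[out_sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("pileup file is not position-sorted on chromosome ", ch)
  }
  new_snv_obs(sites = out_sites,
              match = DT$is_ref,
              r = phred_to_prob(DT$map_qual),
              q = phred_to_prob(DT$base_qual))
}
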