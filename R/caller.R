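#' Turn a decoded state path into per-site SNV calls
#'
#' Combines the decoded genotype state, the posterior state probabilities
#' and the minimum-valid-coverage (MVC) gate into one call per site. A site
#' is reported as an SNV iff its decoded state is ab or bb AND its retained
#' coverage reaches `filt$mvc`; sites failing the gate keep their decoded
#' state but are never flagged as SNV. The MVC gate is applied after
#' decoding -- low-coverage sites still inform the chain.
#'
#' @param obs An [snv_obs] observation set.
#' @param path Integer state path from [viterbi_decode()] (its `path`
#'   element), aligned with `obs`.
#' @param cache An `hmm_trellis` from [forward_backward()] under the same
#'   parameters, aligned with `obs`.
#' @param filt A [filter_config()] supplying `mvc`.
#' @return A data frame with one row per site: `chrom`, `pos`, `ref`,
#'   `alt` (most frequent retained non-reference allele, `NA` when none),
#'   `depth` (retained coverage), `state` (aa/ab/bb), `p_aa`, `p_ab`,
#'   `p_bb` (posteriors), `mvc_pass`, `is_snv`.
#' @export
call_sites <- function(obs, path, cache, filt = filter_config()) {
  stopifnot(inherits(obs, "snv_obs"))
  T_ <- length(obs)
  if (length(path) != T_ || nrow(cache$state_posterior) != T_)
    stop("path, cache and observation sequence must have equal length")
  if (!all(path %in% 1:3)) stop("path must contain states 1..3")
  mvc_pass <- obs$sites$L >= filt$mvc
  data.frame(
    chrom = obs$sites$chrom,
    pos = obs$sites$pos,
    ref = obs$sites$ref,
    alt = obs$sites$alt,
    depth = obs$sites$L,
    state = STATE_LABELS[path],
    p_aa = cache$state_posterior[, 1L],
    p_ab = cache$state_posterior[, 2L],
    p_bb = cache$state_posterior[, 3L],
    mvc_pass = mvc_pass,
    is_snv = path >= 2L & mvc_pass,
    stringsAsFactors = FALSE)
}

#' Write (and read back) calls as a TSV table
#'
#' One header line plus one row per site; posteriors are printed with six
#' decimal places. Output bytes are deterministic for fixed input.
#'
#' @param calls A call data frame from [call_sites()].
#' @param path Output file.
#' @return `path`, invisibly; `read_calls_tsv` returns the data frame.
#' @export
write_calls_tsv <- function(calls, path) {
  header <- paste(c("chrom", "pos", "ref", "alt", "depth", "state",
                    "p_aa", "p_ab", "p_bb", "mvc_pass", "is_snv"),
                  collapse = "\t")
  rows <- sprintf("%s\t%d\t%s\t%s\t%d\t%s\t%.6f\t%.6f\t%.6f\t%d\t%d",
                  calls$chrom, calls$pos, calls$ref,
                  ifelse(is.na(calls$alt), ".", calls$alt),
                  calls$depth, calls$state,
                  calls$p_aa, calls$p_ab, calls$p_bb,
                  as.integer(calls$mvc_pass), as.integer(calls$is_snv))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character", ref = "character",
                                         alt = "character", state = "character"))
  df$alt[df$alt == "."] <- NA_character_
  df$mvc_pass <- as.logical(df$mvc_pass)
  df$is_snv <- as.logical(df$is_snv)
  df
}

#' Write SNV calls as a minimal VCFv4.2 file
#'
#' Emits only sites flagged as SNVs. Genotypes map ab to `0/1` and bb to
#' `1/1`; `QUAL` is `-10 log10(1 - posterior of the called state)`, capped
#' at 9999. SNV sites without a defined alternate allele are skipped with a
#' warning.
#'
#' @param calls A call data frame from [call_sites()].
#' @param path Output file.
#' @param reference_name Name recorded in the `##reference` header line.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, reference_name = "unknown",
                            sample_name = "SAMPLE") {
  snv <- calls[calls$is_snv, , drop = FALSE]
  no_alt <- is.na(snv$alt)
  if (any(no_alt)) {
    warning(sum(no_alt), " SNV site(s) without a defined alternate allele skipped")
    snv <- snv[!no_alt, , drop = FALSE]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hmmsnv",
    paste0("##reference=", reference_name),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Retained read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
  if (nrow(snv)) {
    p_state <- ifelse(snv$state == "ab", snv$p_ab, snv$p_bb)
    qual <- -10 * log10(pmax(1 - p_state, 0))
    qual <- pmin(qual, 9999)
    gt <- ifelse(snv$state == "ab", "0/1", "1/1")
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tDP=%d\tGT\t%s",
                    snv$chrom, snv$pos, snv$ref, snv$alt, qual, snv$depth, gt)
  } else rows <- character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}
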