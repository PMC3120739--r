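# ---- bisulfite clone-sequencing QC -------------------------------------
#
# Clones of a bisulfite PCR product are compared position-by-position with
# the unconverted reference strand. Cytosines in the reference fall into two
# classes: CpG cytosines, where a retained C in the clone is methylation
# signal, and non-CpG cytosines, where a T in the clone measures bisulfite
# conversion efficiency.

#' Round half up to a given number of decimals
#'
#' Pooled percentages are reported with round-half-up semantics (not base R's
#' banker's rounding), computed from pooled counts.
#'
#' @param x numeric.
#' @param digits decimals (default 1).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Partition reference cytosines into CpG and non-CpG positions
#'
#' @param reference unconverted reference strand sequence.
#' @return list with integer vectors \code{cpg} and \code{noncpg}
#'   (disjoint, exhaustive over all C positions).
#' @examples
#' classify_cytosines("ACGTCA")  # cpg = 2, noncpg = 5
#' @export
classify_cytosines <- function(reference) {
  reference <- check_dna(reference, "reference")
  chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  all_c <- which(chars == "C")
  cpg <- cpg_sites(reference)
  list(cpg = cpg, noncpg = setdiff(all_c, cpg))
}

#' Score one clone against its unconverted reference
#'
#' Positional (gap-free) comparison: clone and reference must have equal
#' length; clones with indels are rejected rather than mis-scored. At each
#' reference CpG-C position a clone C counts as retained (methylated) and a
#' clone T as converted; at each non-CpG-C position a clone T counts as
#' converted and a clone C as a conversion failure. Any other base at a
#' cytosine position is counted in \code{other_mismatches} and enters
#' neither numerator.
#'
#' @param clone clone sequence (same strand and length as the reference).
#' @param reference unconverted reference sequence.
#' @param clone_id identifier recorded in the score.
#' @return object of class \code{clone_score}: list with \code{clone_id},
#'   \code{cpg_retained}, \code{cpg_total}, \code{noncpg_converted},
#'   \code{noncpg_total}, \code{other_mismatches}.
#' @export
score_clone <- function(clone, reference, clone_id = "clone") {
  clone <- check_dna(clone, "clone")
  reference <- check_dna(reference, "reference")
  if (nchar(clone) != nchar(reference)) {
    stop(sprintf("clone %s length (%d) differs from reference length (%d); indels are not supported",
                 clone_id, nchar(clone), nchar(reference)), call. = FALSE)
  }
  cl <- strsplit(clone, "", fixed = TRUE)[[1L]]
  sites <- classify_cytosines(reference)
  cpg_b <- cl[sites$cpg]
  non_b <- cl[sites$noncpg]
  structure(list(
    clone_id = clone_id,
    cpg_retained = sum(cpg_b == "C"),
    cpg_total = length(sites$cpg),
    noncpg_converted = sum(non_b == "T"),
    noncpg_total = length(sites$noncpg),
    other_mismatches = sum(!cpg_b %in% c("C", "T")) + sum(!non_b %in% c("C", "T"))
  ), class = "clone_score")
}

#' Aggregate clone scores into a per-sample report
#'
#' Percentages are computed from pooled numerators and denominators across
#' clones (never as a mean of per-clone percentages) and reported to one
#' decimal, round-half-up: 223/224 pooled CpG retention gives 99.6 and
#' 548/704 pooled conversion gives 77.8.
#'
#' @param scores list of \code{\link{score_clone}} results.
#' @param sample_id sample identifier.
#' @return object of class \code{sample_clone_report}: list with
#'   \code{sample_id}, \code{n_clones}, pooled counts, \code{cpg_retention_pct},
#'   \code{noncpg_conversion_pct} and \code{per_clone} (data.frame).
#' @export
aggregate_clones <- function(scores, sample_id = "sample") {
  if (length(scores) == 0L) stop("no clone scores to aggregate", call. = FALSE)
  stopifnot(all(vapply(scores, inherits, logical(1L), "clone_score")))
  per <- do.call(rbind, lapply(scores, function(s)
    data.frame(clone_id = s$clone_id, cpg_retained = s$cpg_retained,
               cpg_total = s$cpg_total, noncpg_converted = s$noncpg_converted,
               noncpg_total = s$noncpg_total,
               other_mismatches = s$other_mismatches)))
  cpg_ret <- sum(per$cpg_retained); cpg_tot <- sum(per$cpg_total)
  non_conv <- sum(per$noncpg_converted); non_tot <- sum(per$noncpg_total)
  structure(list(
    sample_id = sample_id,
    n_clones = nrow(per),
    cpg_retained = cpg_ret, cpg_total = cpg_tot,
    noncpg_converted = non_conv, noncpg_total = non_tot,
    cpg_retention_pct = if (cpg_tot > 0) round_half_up(100 * cpg_ret / cpg_tot) else NA_real_,
    noncpg_conversion_pct = if (non_tot > 0) round_half_up(100 * non_conv / non_tot) else NA_real_,
    per_clone = per
  ), class = "sample_clone_report")
}

#' @export
print.sample_clone_report <- function(x, ...) {
  cat(sprintf(
    "<sample_clone_report> %s: %d clones; CpG retention %s%% (%d/%d); non-CpG conversion %s%% (%d/%d)\n",
    x$sample_id, x$n_clones, format(x$cpg_retention_pct), x$cpg_retained,
    x$cpg_total, format(x$noncpg_conversion_pct), x$noncpg_converted,
    x$noncpg_total))
  invisible(x)
}

#' Call the methylation status of a sample from its clone report
#'
#' \code{"fully-methylated"} when pooled CpG retention is at or above the
#' high threshold, \code{"unmethylated"} at or below the low threshold,
#' otherwise \code{"partially-methylated"}. Samples whose pooled non-CpG
#' conversion falls below the QC floor are flagged (incomplete bisulfite
#' conversion inflates apparent methylation) but still called: validated
#' clone sets with conversion efficiencies below 80% can still be
#' unambiguously methylated at every CpG.
#'
#' @param report a \code{\link{aggregate_clones}} result.
#' @param high_threshold percent retention at/above which the sample is
#'   fully methylated (default 90).
#' @param low_threshold percent retention at/below which the sample is
#'   unmethylated (default 10).
#' @param conversion_floor QC floor on non-CpG conversion percent
#'   (default 70); below it a \code{"low-conversion-efficiency"} flag is set.
#' @return list with \code{call} and \code{flags}.
#' @export
call_sample <- function(report, high_threshold = 90, low_threshold = 10,
                        conversion_floor = 70) {
  stopifnot(inherits(report, "sample_clone_report"))
  flags <- character(0)
  if (!is.na(report$noncpg_conversion_pct) &&
      report$noncpg_conversion_pct < conversion_floor) {
    flags <- c(flags, "low-conversion-efficiency")
  }
  r <- report$cpg_retention_pct
  call <- if (r >= high_threshold) "fully-methylated"
          else if (r <= low_threshold) "unmethylated"
          else "partially-methylated"
  list(call = call, flags = flags)
}

#' Read clone sequences from FASTA and score them against a reference
#'
#' @param clones_path FASTA of clone sequences.
#' @param reference_path FASTA with a single unconverted reference record.
#' @param sample_id sample identifier.
#' @return a \code{\link{aggregate_clones}} report.
#' @export
clone_qc_fasta <- function(clones_path, reference_path, sample_id = "sample") {
  ref <- Biostrings::readDNAStringSet(reference_path)
  if (length(ref) != 1L) stop("reference FASTA must contain exactly one record",
                              call. = FALSE)
  clones <- Biostrings::readDNAStringSet(clones_path)
  if (length(clones) == 0L) stop("no clones in ", clones_path, call. = FALSE)
  refseq <- as.character(ref[[1L]])
  scores <- lapply(seq_along(clones), function(i)
    score_clone(as.character(clones[[i]]), refseq,
                clone_id = sub("\\s.*$", "", names(clones)[i])))
  aggregate_clones(scores, sample_id = sample_id)
}
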