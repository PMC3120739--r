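# ---- MethyLight relative copy number quantification --------------------
#
# Replicate Ct values are averaged per (sample, target); the relative copy
# number of the methylated target is 2^-(Ct_target - Ct_reference) against a
# CpG-free reference gene, then standardized to the fully methylated
# positive control. "Not detected" is encoded explicitly as NA (never as
# Ct 45) and quantifies as RCN 0 with a flag.

#' Read a Ct table from delimited text
#'
#' Expected columns: \code{sample_id}, \code{target}, \code{replicate},
#' \code{ct}; the string \code{"ND"} (case-insensitive) or an empty field
#' encodes a not-detected well and is read as \code{NA}.
#'
#' @param path TSV/CSV file.
#' @param sep field separator (default tab).
#' @param max_cycles maximum valid Ct (default 45, the standard 45-cycle
#'   thermal profile).
#' @return data.frame of well records.
#' @export
read_ct_table <- function(path, sep = "\t", max_cycles = 45) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "integer", "character"))
  need <- c("sample_id", "target", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ct_raw <- trimws(df$ct)
  nd <- toupper(ct_raw) %in% c("ND", "") | is.na(ct_raw)
  ct <- suppressWarnings(as.numeric(ct_raw))
  if (any(!nd & is.na(ct))) {
    stop("unparseable Ct value(s): ",
         paste(unique(ct_raw[!nd & is.na(ct)]), collapse = ", "),
         call. = FALSE)
  }
  ct[nd] <- NA_real_
  if (any(!is.na(ct) & (ct <= 0 | ct > max_cycles))) {
    stop("Ct values must lie in (0, ", max_cycles, "]", call. = FALSE)
  }
  df$ct <- ct
  df[, need]
}

#' Collapse replicate wells to one Ct per sample and target
#'
#' The arithmetic mean of the detected Ct values is used (replicates are
#' averaged on the Ct scale, not the copy-number scale). A (sample, target)
#' pair whose wells are all not-detected collapses to \code{NA} with an
#' \code{"all-replicates-not-detected"} flag. Replicate pairs spreading more
#' than \code{spread_warn} cycles are flagged \code{"replicate-spread"}.
#'
#' @param wells data.frame as from \code{\link{read_ct_table}} (ct column
#'   numeric, \code{NA} = not detected).
#' @param spread_warn flag threshold on the within-pair Ct range in cycles
#'   (default 1.5).
#' @return data.frame with columns \code{sample_id}, \code{target},
#'   \code{ct} (mean of detected replicates or NA), \code{n_detected},
#'   \code{n_wells}, \code{flags}.
#' @export
collapse_replicates <- function(wells, spread_warn = 1.5) {
  stopifnot(all(c("sample_id", "target", "ct") %in% names(wells)))
  key <- interaction(wells$sample_id, wells$target, drop = TRUE, sep = "\r")
  pieces <- lapply(split(wells, key), function(g) {
    det <- g$ct[!is.na(g$ct)]
    flags <- character(0)
    if (length(det) == 0L) flags <- c(flags, "all-replicates-not-detected")
    if (length(det) >= 2L && diff(range(det)) > spread_warn) {
      flags <- c(flags, "replicate-spread")
    }
    data.frame(sample_id = g$sample_id[1L], target = g$target[1L],
               ct = if (length(det)) mean(det) else NA_real_,
               n_detected = length(det), n_wells = nrow(g),
               flags = paste(flags, collapse = ";"))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$sample_id, out$target), ]
}

#' Relative copy number from a pair of Ct values
#'
#' Computes \code{efficiency^-(ct_target - ct_reference)}; with the default
#' efficiency of 2 this is the pure 2^-dCt model (no PCR-efficiency
#' correction). A not-detected target (\code{NA}) quantifies as 0 so that
#' downstream classification treats it as methylation-negative.
#'
#' @param ct_target methylation-target Ct, or \code{NA} for not detected.
#' @param ct_reference reference-gene Ct (must be detected).
#' @param efficiency amplification base (default 2).
#' @return non-negative relative copy number.
#' @examples
#' relative_copy_number(32, 30)  # 0.25
#' @export
relative_copy_number <- function(ct_target, ct_reference, efficiency = 2) {
  if (is.na(ct_reference)) {
    stop("reference Ct not detected: quantification impossible", call. = FALSE)
  }
  if (is.na(ct_target)) return(0)
  efficiency^-(ct_target - ct_reference)
}

#' Standardize a relative copy number to the positive control
#'
#' @param rcn_sample raw RCN of a sample.
#' @param rcn_positive_control raw RCN of the fully methylated positive
#'   control (must be positive).
#' @return standardized RCN (the control itself standardizes to 1).
#' @export
standardize_rcn <- function(rcn_sample, rcn_positive_control) {
  if (is.na(rcn_positive_control) || rcn_positive_control <= 0) {
    stop("positive-control RCN must be > 0 (control failure)", call. = FALSE)
  }
  rcn_sample / rcn_positive_control
}

#' Quantify a MethyLight batch with run controls
#'
#' Collapses replicates, validates the run controls, computes per-sample raw
#' RCN of the methylation target against the reference gene, and
#' standardizes to the positive control. The run is rejected when the
#' negative control's methylation target amplifies earlier than
#' \code{max_cycles - margin} cycles (contamination signature) or the
#' positive control's methylation target is not detected.
#'
#' @param wells well-level Ct data.frame (see \code{\link{read_ct_table}}).
#' @param target name of the methylation assay target in the table.
#' @param reference name of the reference-gene target (default
#'   \code{"COL2A1"}).
#' @param positive_id,negative_id sample ids of the methylated positive and
#'   negative run controls.
#' @param max_cycles cycle ceiling (default 45).
#' @param margin negative-control rejection margin in cycles (default 5).
#' @param efficiency amplification base (default 2).
#' @param spread_warn replicate-spread flag threshold (default 1.5 cycles).
#' @return data.frame of class \code{rcn_result}: \code{sample_id},
#'   \code{ct_target}, \code{ct_reference}, \code{rcn_raw},
#'   \code{rcn_standardized}, \code{flags}.
#' @export
quantify_batch <- function(wells, target, reference = "COL2A1",
                           positive_id, negative_id,
                           max_cycles = 45, margin = 5, efficiency = 2,
                           spread_warn = 1.5) {
  coll <- collapse_replicates(wells, spread_warn = spread_warn)
  if (!target %in% coll$target || !reference %in% coll$target) {
    stop("targets '", target, "' and '", reference,
         "' must both be present in the table", call. = FALSE)
  }
  get_ct <- function(sid, tgt) {
    r <- coll[coll$sample_id == sid & coll$target == tgt, ]
    if (nrow(r) == 0L) return(NULL)
    r
  }
  for (ctl in c(positive_id, negative_id)) {
    if (!ctl %in% coll$sample_id) {
      stop("control sample '", ctl, "' missing from the batch", call. = FALSE)
    }
  }
  neg_t <- get_ct(negative_id, target)
  if (!is.null(neg_t) && !is.na(neg_t$ct) && neg_t$ct < max_cycles - margin) {
    stop(sprintf(
      "run rejected: negative control '%s' amplified the methylation target at Ct %.2f (< %g)",
      negative_id, neg_t$ct, max_cycles - margin), call. = FALSE)
  }
  pos_t <- get_ct(positive_id, target)
  pos_r <- get_ct(positive_id, reference)
  if (is.null(pos_t) || is.na(pos_t$ct) || is.null(pos_r) || is.na(pos_r$ct)) {
    stop("run rejected: positive control '", positive_id,
         "' not detected", call. = FALSE)
  }
  rcn_pos <- relative_copy_number(pos_t$ct, pos_r$ct, efficiency)
  samples <- unique(coll$sample_id)
  rows <- lapply(samples, function(sid) {
    flags <- character(0)
    tr <- get_ct(sid, target)
    rr <- get_ct(sid, reference)
    if (is.null(rr)) {
      stop("sample '", sid, "' has no reference-gene wells", call. = FALSE)
    }
    for (g in list(tr, rr)) {
      if (!is.null(g) && nzchar(g$flags)) {
        flags <- c(flags, strsplit(g$flags, ";", fixed = TRUE)[[1L]])
      }
    }
    if (is.na(rr$ct)) {
      flags <- c(flags, "invalid-sample-reference-not-detected")
      rcn_raw <- NA_real_
    } else {
      ct_t <- if (is.null(tr)) NA_real_ else tr$ct
      if (is.na(ct_t)) flags <- c(flags, "target-not-detected")
      rcn_raw <- relative_copy_number(ct_t, rr$ct, efficiency)
    }
    data.frame(sample_id = sid,
               ct_target = if (is.null(tr)) NA_real_ else tr$ct,
               ct_reference = rr$ct,
               rcn_raw = rcn_raw,
               rcn_standardized = if (is.na(rcn_raw)) NA_real_ else
                 standardize_rcn(rcn_raw, rcn_pos),
               flags = paste(unique(flags), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rcn_result", class(out))
  out
}
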