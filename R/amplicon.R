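# ---- TSS-relative coordinate arithmetic --------------------------------
#
# Coordinates are numbered relative to the transcription start site: +1 is
# the first transcribed base, -1 the base immediately upstream, and there is
# no position 0. Intervals are 1-based and inclusive at both ends.

# Collapse the missing 0 so the axis becomes ordinary integers.
.tss_linear <- function(t) ifelse(t > 0, t, t + 1L)

#' Convert a 1-based sequence index to a TSS-relative coordinate
#'
#' @param pos 1-based index (or vector) within the region sequence.
#' @param tss_offset 1-based index of the +1 base.
#' @return TSS-relative coordinate(s); never 0.
#' @export
offset_to_tss <- function(pos, tss_offset) {
  d <- pos - tss_offset
  ifelse(d >= 0, d + 1L, d)
}

#' Convert a TSS-relative coordinate to a 1-based sequence index
#'
#' @param tss TSS-relative coordinate(s); 0 is invalid.
#' @param tss_offset 1-based index of the +1 base.
#' @return 1-based index/indices.
#' @export
tss_to_offset <- function(tss, tss_offset) {
  if (any(tss == 0)) stop("TSS numbering has no position 0", call. = FALSE)
  ifelse(tss > 0, tss_offset + tss - 1L, tss_offset + tss)
}

#' Construct a TSS-relative amplicon interval
#'
#' @param start_tss TSS-relative position of the first base.
#' @param end_tss TSS-relative position of the last base.
#' @param strand \code{"sense"} or \code{"antisense"}.
#' @return object of class \code{amplicon_interval}.
#' @export
amplicon_interval <- function(start_tss, end_tss,
                              strand = c("sense", "antisense")) {
  strand <- match.arg(strand)
  start_tss <- as.integer(start_tss); end_tss <- as.integer(end_tss)
  if (start_tss == 0L || end_tss == 0L) {
    stop("TSS numbering has no position 0", call. = FALSE)
  }
  if (start_tss > end_tss) stop("start_tss must be <= end_tss", call. = FALSE)
  structure(list(start_tss = start_tss, end_tss = end_tss, strand = strand),
            class = "amplicon_interval")
}

#' @export
print.amplicon_interval <- function(x, ...) {
  cat(sprintf("<amplicon_interval> %+d ~ %+d (%s strand, %d bp)\n",
              x$start_tss, x$end_tss, x$strand, interval_length(x)))
  invisible(x)
}

#' Inclusive length of a TSS-relative interval
#'
#' Because TSS numbering skips 0, a span crossing the TSS is one shorter than
#' naive subtraction suggests: (+238, +307) is 70 bp, (-5, +5) is 10 bp.
#'
#' @param iv an \code{\link{amplicon_interval}}.
#' @return integer length in bp.
#' @examples
#' interval_length(amplicon_interval(238, 307))  # 70
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "amplicon_interval"))
  .tss_linear(iv$end_tss) - .tss_linear(iv$start_tss) + 1L
}

#' Overlap between two TSS-relative intervals
#'
#' Computed on genomic coordinates, strand-agnostic: amplicons on opposite
#' strands overlap wherever their genomic footprints share positions.
#'
#' @param a,b \code{\link{amplicon_interval}} objects on the same TSS scale.
#' @return number of shared positions (0 if disjoint).
#' @examples
#' interval_overlap(amplicon_interval(157, 272), amplicon_interval(133, 283))
#' @export
interval_overlap <- function(a, b) {
  stopifnot(inherits(a, "amplicon_interval"), inherits(b, "amplicon_interval"))
  lo <- max(.tss_linear(a$start_tss), .tss_linear(b$start_tss))
  hi <- min(.tss_linear(a$end_tss), .tss_linear(b$end_tss))
  max(0L, hi - lo + 1L)
}

# ---- assays -------------------------------------------------------------

#' Bundle primers and probe into a MethyLight assay
#'
#' @param name assay name.
#' @param forward,reverse,probe \code{oligo} objects with matching roles.
#' @param target_strand strand of the bisulfite template the assay was
#'   designed against.
#' @param reference \code{TRUE} for a methylation-neutral control assay (a
#'   CpG-free reference gene such as COL2A1); such assays are expected to
#'   carry no discriminating bases.
#' @param nominal_amplicon optional length-2 integer vector of published
#'   TSS-relative amplicon coordinates, kept as metadata.
#' @param nominal_length optional published amplicon length (bp).
#' @return object of class \code{assay}.
#' @export
assay <- function(name, forward, reverse, probe,
                  target_strand = c("sense", "antisense"),
                  reference = FALSE,
                  nominal_amplicon = NULL, nominal_length = NULL) {
  target_strand <- match.arg(target_strand)
  for (o in list(forward, reverse, probe)) stopifnot(inherits(o, "oligo"))
  if (forward$role != "forward" || reverse$role != "reverse" ||
      probe$role != "probe") {
    stop("oligo roles inconsistent with their slots in assay ", name,
         call. = FALSE)
  }
  n_disc <- oligo_cpg_count(forward) + oligo_cpg_count(reverse) +
    oligo_cpg_count(probe)
  if (reference && n_disc > 0L) {
    warning("reference assay ", name, " carries discriminating CpG bases",
            call. = FALSE)
  }
  if (!reference && n_disc == 0L) {
    warning("assay ", name, ": no methylation discrimination ",
            "(zero discriminating CpG bases in all oligos)", call. = FALSE)
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 probe = probe, target_strand = target_strand,
                 reference = reference,
                 nominal_amplicon = nominal_amplicon,
                 nominal_length = nominal_length),
            class = "assay")
}

#' @export
print.assay <- function(x, ...) {
  cat(sprintf("<assay> %s (%s strand%s)\n", x$name, x$target_strand,
              if (x$reference) ", reference" else ""))
  print(x$forward); print(x$reverse); print(x$probe)
  invisible(x)
}

#' Read assay definitions from a YAML config file
#'
#' The config holds a top-level \code{assays:} list; each entry has
#' \code{name}, \code{target_strand}, optional \code{reference},
#' optional \code{amplicon_tss} (published coordinates) and
#' \code{nominal_length}, and \code{forward}/\code{reverse}/\code{probe}
#' blocks with \code{name}, annotated \code{sequence}, optional \code{label},
#' \code{search} and \code{discriminating}. The package ships the three
#' published assays in \code{system.file("extdata", "assays.yml",
#' package = "methylightr")}.
#'
#' @param path YAML file.
#' @return named list of \code{\link{assay}} objects.
#' @export
read_assays <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$assays)) stop("no 'assays' entry in ", path, call. = FALSE)
  out <- lapply(cfg$assays, function(a) {
    get_oligo <- function(role) {
      blk <- a[[role]]
      if (is.null(blk)) stop("assay ", a$name, " lacks a ", role, " oligo",
                             call. = FALSE)
      parse_oligo(blk$sequence, role = role,
                  name = if (is.null(blk$name)) paste(a$name, role) else blk$name,
                  label = blk$label,
                  discriminating = blk$discriminating,
                  search = blk$search)
    }
    assay(name = a$name,
          forward = get_oligo("forward"),
          reverse = get_oligo("reverse"),
          probe = get_oligo("probe"),
          target_strand = if (is.null(a$target_strand)) "sense" else a$target_strand,
          reference = isTRUE(a$reference),
          nominal_amplicon = if (!is.null(a$amplicon_tss)) as.integer(a$amplicon_tss),
          nominal_length = a$nominal_length)
  })
  names(out) <- vapply(out, `[[`, character(1L), "name")
  out
}

# Map a template-coordinate interval [i, j] to sense-strand sequence indices.
.template_to_sense <- function(i, j, template) {
  if (template$strand == "sense") c(i, j)
  else c(template$region_length - j + 1L, template$region_length - i + 1L)
}

#' Derive the amplicon interval of an assay on a template
#'
#' Places forward and reverse primers on the template (each must have exactly
#' one perfect hit, forward upstream of reverse) and returns the interval
#' from the forward primer's 5' base through the reverse primer's 5' base
#' (outermost coordinates, the standard qPCR amplicon convention), expressed
#' TSS-relative. The probe must lie strictly inside the primer span; if it
#' does not (or has no perfect hit) a warning is raised and recorded.
#'
#' @param assay an \code{\link{assay}}.
#' @param template a \code{bisulfite_template}.
#' @return \code{\link{amplicon_interval}} with attributes
#'   \code{template_start}, \code{template_end} (1-based template indices)
#'   and \code{probe_inside} (logical).
#' @export
amplicon_of <- function(assay, template) {
  stopifnot(inherits(assay, "assay"), inherits(template, "bisulfite_template"))
  fh <- locate_oligo(assay$forward, template)
  rh <- locate_oligo(assay$reverse, template)
  if (nrow(fh) != 1L || nrow(rh) != 1L) {
    stop(sprintf(
      "assay %s: need exactly one perfect hit per primer on %s|%s (forward: %d, reverse: %d)",
      assay$name, template$strand, template$assumption, nrow(fh), nrow(rh)),
      call. = FALSE)
  }
  m_f <- nchar(assay$forward$sequence)
  m_r <- nchar(assay$reverse$sequence)
  left <- fh$position                   # forward primer 5' base
  right <- rh$position + m_r - 1L       # reverse primer 5' base (revcomp hit)
  if (left >= rh$position) {
    stop("assay ", assay$name, ": primers inverted on template (forward not upstream of reverse)",
         call. = FALSE)
  }
  ph <- locate_oligo(assay$probe, template)
  probe_inside <- FALSE
  if (nrow(ph) >= 1L) {
    p0 <- ph$position[1L]
    p1 <- p0 + nchar(assay$probe$sequence) - 1L
    probe_inside <- (p0 > left && p1 < right)
  }
  if (!probe_inside) {
    warning("assay ", assay$name,
            ": probe has no perfect hit strictly inside the primer span",
            call. = FALSE)
  }
  sense <- .template_to_sense(left, right, template)
  iv <- amplicon_interval(offset_to_tss(sense[1L], template$tss_offset),
                          offset_to_tss(sense[2L], template$tss_offset),
                          strand = template$strand)
  attr(iv, "template_start") <- left
  attr(iv, "template_end") <- right
  attr(iv, "probe_inside") <- probe_inside
  iv
}

# ---- specificity report -------------------------------------------------

#' Methylation-specificity report for an assay
#'
#' Scans all three oligos against the four bisulfite templates of a region
#' and reports the best hit per oligo per template (at any mismatch count, so
#' near-specific designs remain visible). The verdict is
#' \code{"methylation-specific"} when all three oligos hit the methylated
#' template of the target strand perfectly \emph{and} every discriminating
#' base mismatches on the corresponding unmethylated template (the
#' discriminating C faces a converted T). A reference assay with identical
#' hits on the methylated and unmethylated templates is
#' \code{"methylation-neutral"}; anything else is \code{"not-specific"}.
#'
#' @param assay an \code{\link{assay}}.
#' @param templates list of four templates from
#'   \code{\link{bisulfite_templates}}.
#' @return object of class \code{specificity_report}: list with
#'   \code{assay}, \code{target_strand}, \code{verdict}, \code{hits}
#'   (data.frame: template, strand, assumption, oligo, role, position,
#'   orientation, mismatches, mismatch_at_cpg), \code{warnings}.
#' @export
specificity_report <- function(assay, templates) {
  stopifnot(inherits(assay, "assay"))
  need <- c("sense_methylated", "sense_unmethylated",
            "antisense_methylated", "antisense_unmethylated")
  if (!all(need %in% names(templates))) {
    stop("templates must be the four-template list from bisulfite_templates()",
         call. = FALSE)
  }
  oligos <- list(assay$forward, assay$reverse, assay$probe)
  warnings <- character(0)
  rows <- list()
  for (tn in need) {
    tpl <- templates[[tn]]
    for (o in oligos) {
      h <- best_oligo_hit(o, tpl)
      rows[[length(rows) + 1L]] <- data.frame(
        template = tn, strand = tpl$strand, assumption = tpl$assumption,
        oligo = o$name, role = o$role,
        position = if (nrow(h)) h$position else NA_integer_,
        orientation = if (nrow(h)) h$orientation else NA_character_,
        mismatches = if (nrow(h)) h$mismatches else NA_integer_,
        mismatch_at_cpg = if (nrow(h)) h$mismatch_at_cpg else NA_integer_)
    }
  }
  hits <- do.call(rbind, rows)
  n_disc_total <- sum(vapply(oligos, oligo_cpg_count, integer(1L)))
  if (!assay$reference && n_disc_total == 0L) {
    warnings <- c(warnings, "no methylation discrimination")
  }
  m_name <- paste0(assay$target_strand, "_methylated")
  u_name <- paste0(assay$target_strand, "_unmethylated")
  mh <- hits[hits$template == m_name, ]
  uh <- hits[hits$template == u_name, ]
  perfect_on_m <- all(!is.na(mh$mismatches)) && all(mh$mismatches == 0L)
  if (assay$reference) {
    neutral <- perfect_on_m && !any(is.na(uh$position)) &&
      all(mh$position == uh$position) && all(mh$mismatches == uh$mismatches)
    verdict <- if (neutral) "methylation-neutral" else "not-specific"
  } else {
    disc_fail <- TRUE
    for (o in oligos) {
      if (oligo_cpg_count(o) == 0L) next
      r_m <- mh[mh$oligo == o$name, ]
      if (is.na(r_m$position) || r_m$mismatches != 0L) { disc_fail <- FALSE; break }
      # evaluate the oligo at the same placement on the unmethylated template
      sc <- .oligo_scans(o, templates[[u_name]], orientation = r_m$orientation)
      at <- sc[sc$position == r_m$position, , drop = FALSE]
      n_sens <- length(.sensitive_positions(o, r_m$orientation))
      if (nrow(at) != 1L || at$mismatch_at_cpg != n_sens) {
        disc_fail <- FALSE; break
      }
    }
    verdict <- if (perfect_on_m && disc_fail && n_disc_total > 0L) {
      "methylation-specific"
    } else {
      "not-specific"
    }
  }
  structure(list(assay = assay$name, target_strand = assay$target_strand,
                 verdict = verdict, hits = hits, warnings = warnings),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("<specificity_report> %s: %s (target %s strand)\n",
              x$assay, x$verdict, x$target_strand))
  print(x$hits, row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
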