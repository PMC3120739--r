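# ---- oligo parsing and annotation --------------------------------------

#' Parse an annotated primer/probe sequence
#'
#' MethyLight oligos are written in a case-annotation dialect: uppercase C
#' (and uppercase G on reverse-orientation oligos) marks a CpG-derived
#' discriminating base, i.e. a position that pairs correctly only when the
#' template CpG was methylated and therefore escaped conversion. Whitespace,
#' digits, 5'/3' decorations, dashes and asterisks are stripped before
#' parsing.
#'
#' Oligos supplied in plain (single) case carry no case annotation; for those
#' the discriminating positions may be given explicitly via
#' \code{discriminating}.
#'
#' @param text annotated sequence, e.g. \code{"CgCgg tCgtg gttag ttagt"}.
#' @param role one of \code{"forward"}, \code{"reverse"}, \code{"probe"}.
#' @param name oligo name.
#' @param label optional dye/quencher text (e.g. \code{"6FAM/TAMRA"}).
#' @param discriminating optional integer positions (1-based, on the oligo)
#'   overriding the case annotation.
#' @param search optional search orientation override:
#'   \code{"asis"}, \code{"revcomp"} or \code{"auto"}; defaults by role
#'   (forward: asis, reverse: revcomp, probe: auto).
#' @return object of class \code{oligo}: list with \code{name},
#'   \code{sequence} (uppercase), \code{role}, \code{label},
#'   \code{discriminating} (positions), \code{search}.
#' @examples
#' o <- parse_oligo("CgCgg tCgtg gttag ttagt", "forward", "ML-Primer-F2")
#' oligo_cpg_count(o)  # 3
#' @export
parse_oligo <- function(text, role = c("forward", "reverse", "probe"),
                        name = "oligo", label = NULL,
                        discriminating = NULL, search = NULL) {
  role <- match.arg(role)
  stripped <- gsub("[][0-9'\"`*().,;:_′″ \t\r\n-]", "", text)
  chars <- strsplit(stripped, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("empty oligo sequence for ", name, call. = FALSE)
  up <- toupper(chars)
  bad <- which(!up %in% .DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("oligo %s: non-base character '%s' after stripping decorations",
                 name, chars[bad[1L]]), call. = FALSE)
  }
  if (is.null(discriminating)) {
    mixed_case <- any(chars %in% c("a", "c", "g", "t")) && any(chars %in% .DNA_ALPHABET)
    discriminating <- if (mixed_case) {
      which(chars %in% c("C", "G"))
    } else {
      integer(0)
    }
  } else {
    discriminating <- sort(unique(as.integer(discriminating)))
    if (any(discriminating < 1L | discriminating > length(chars))) {
      stop("discriminating positions outside oligo for ", name, call. = FALSE)
    }
  }
  if (is.null(search)) {
    search <- switch(role, forward = "asis", reverse = "revcomp", probe = "auto")
  }
  search <- match.arg(search, c("asis", "revcomp", "auto"))
  structure(list(name = name, sequence = paste(up, collapse = ""),
                 role = role, label = label,
                 discriminating = discriminating, search = search),
            class = "oligo")
}

#' Number of discriminating CpG-derived bases in an oligo
#'
#' @param oligo an \code{\link{parse_oligo}} object.
#' @return integer count; 0 for a methylation-neutral (reference) oligo.
#' @export
oligo_cpg_count <- function(oligo) {
  stopifnot(inherits(oligo, "oligo"))
  length(oligo$discriminating)
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> %s [%s] %d nt, %d discriminating CpG base(s)\n",
              x$name, x$role, nchar(x$sequence), oligo_cpg_count(x)))
  invisible(x)
}

# Scan every offset of a query against a template sequence, returning
# mismatch counts and mismatches restricted to the discriminating positions.
.scan_query <- function(query_chars, disc_idx, tpl_chars) {
  m <- length(query_chars)
  n <- length(tpl_chars)
  if (m > n) return(NULL)
  n_off <- n - m + 1L
  mism <- integer(n_off)
  mism_cpg <- integer(n_off)
  for (j in seq_len(m)) {
    neq <- tpl_chars[j:(n_off + j - 1L)] != query_chars[j]
    mism <- mism + neq
    if (j %in% disc_idx) mism_cpg <- mism_cpg + neq
  }
  data.frame(position = seq_len(n_off), mismatches = mism,
             mismatch_at_cpg = mism_cpg)
}

.template_seq <- function(template) {
  if (inherits(template, "bisulfite_template")) template$converted
  else check_dna(template, "template")
}

#' Locate an oligo on a bisulfite template
#'
#' Forward primers and (by default) probes are searched in the orientation
#' written; reverse primers are searched as their reverse complement, since
#' they anneal to the strand synthesized from the template. Probes default to
#' \code{"auto"}: both orientations are scanned and the orientation whose best
#' hit has fewer mismatches is reported (TaqMan probes may sit on either
#' product strand).
#'
#' @param oligo an \code{oligo}.
#' @param template a \code{bisulfite_template} (or plain DNA string).
#' @param max_mismatch maximum mismatches for a reported hit (default 0).
#' @param orientation override: \code{"asis"}, \code{"revcomp"},
#'   \code{"auto"}; default taken from the oligo.
#' @return data.frame with one row per hit, sorted by position: columns
#'   \code{position} (1-based start on the template), \code{orientation},
#'   \code{mismatches}, \code{mismatch_at_cpg} (mismatches at discriminating
#'   bases). Zero rows (with a warning) when the oligo is longer than the
#'   template.
#' @export
locate_oligo <- function(oligo, template, max_mismatch = 0L,
                         orientation = NULL) {
  stopifnot(inherits(oligo, "oligo"))
  scans <- .oligo_scans(oligo, template, orientation)
  if (is.null(scans)) {
    warning("oligo ", oligo$name, " is longer than the template; no hits",
            call. = FALSE)
    return(.empty_hits())
  }
  hits <- scans[scans$mismatches <= max_mismatch, , drop = FALSE]
  hits <- hits[order(hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Conversion-sensitive oligo positions for a given search orientation.
# A marked base denotes its CpG dinucleotide; the position actually facing
# the template's methylatable C depends on orientation: searched as-is, a
# marked G preceded by C stands for that C; searched as reverse complement,
# a marked C followed by G stands for that G (whose complement faces the
# template C). Returned unique, in the oligo's own frame.
.sensitive_positions <- function(oligo, orient) {
  d <- oligo$discriminating
  if (length(d) == 0L) return(integer(0))
  ch <- strsplit(oligo$sequence, "", fixed = TRUE)[[1L]]
  m <- length(ch)
  adj <- vapply(d, function(i) {
    if (orient == "asis" && ch[i] == "G" && i > 1L && ch[i - 1L] == "C") i - 1L
    else if (orient == "revcomp" && ch[i] == "C" && i < m && ch[i + 1L] == "G") i + 1L
    else i
  }, integer(1L))
  sort(unique(adj))
}

# Full scan in the orientation(s) implied; returns a data.frame with an
# `orientation` column, or NULL when the oligo does not fit.
.oligo_scans <- function(oligo, template, orientation = NULL) {
  if (is.null(orientation)) orientation <- oligo$search
  orientation <- match.arg(orientation, c("asis", "revcomp", "auto"))
  tpl_chars <- strsplit(.template_seq(template), "", fixed = TRUE)[[1L]]
  m <- nchar(oligo$sequence)
  one <- function(orient) {
    d <- .sensitive_positions(oligo, orient)
    if (orient == "asis") {
      q <- strsplit(oligo$sequence, "", fixed = TRUE)[[1L]]
    } else {
      q <- strsplit(reverse_complement(oligo$sequence), "", fixed = TRUE)[[1L]]
      d <- m - d + 1L
    }
    sc <- .scan_query(q, d, tpl_chars)
    if (is.null(sc)) return(NULL)
    sc$orientation <- orient
    sc[, c("position", "orientation", "mismatches", "mismatch_at_cpg")]
  }
  if (orientation == "auto") {
    a <- one("asis"); b <- one("revcomp")
    if (is.null(a)) return(NULL)
    rbind(a, b)
  } else {
    one(orientation)
  }
}

.empty_hits <- function() {
  data.frame(position = integer(0), orientation = character(0),
             mismatches = integer(0), mismatch_at_cpg = integer(0))
}

#' Best hit of an oligo on a template at any mismatch count
#'
#' Used by specificity reporting so near-specific designs remain visible.
#' Ties on mismatch count are broken toward the leftmost position.
#'
#' @inheritParams locate_oligo
#' @return one-row data.frame like \code{\link{locate_oligo}} output, or zero
#'   rows if the oligo does not fit on the template.
#' @export
best_oligo_hit <- function(oligo, template, orientation = NULL) {
  scans <- .oligo_scans(oligo, template, orientation)
  if (is.null(scans) || nrow(scans) == 0L) return(.empty_hits())
  scans <- scans[order(scans$mismatches, scans$position), , drop = FALSE]
  out <- scans[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
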