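# ---- sequence primitives -----------------------------------------------

.DNA_ALPHABET <- c("A", "C", "G", "T")

#' Validate a DNA string
#'
#' Uppercases the input and checks that every character is one of A/C/G/T.
#' Ambiguity codes (N, Y, R, ...) are rejected: bisulfite template modelling
#' requires fully resolved bases.
#'
#' @param seq single character string.
#' @param what label used in error messages.
#' @return the normalized (uppercase) sequence.
#' @keywords internal
check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  up <- toupper(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  up
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick reverse complement over the strict A/C/G/T alphabet.
#'
#' @param seq DNA string (A/C/G/T, case-insensitive).
#' @return reverse complement, uppercase.
#' @examples
#' reverse_complement("ACGT")  # palindrome -> "ACGT"
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- check_dna(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Enumerate CpG sites on a strand
#'
#' Returns the 1-based positions of the cytosine of every CpG dinucleotide.
#' The CpG cytosine is the methylatable base; these positions drive both the
#' conversion model and clone scoring.
#'
#' @param seq DNA string.
#' @return integer vector of positions p with substr(seq, p, p+1) == "CG",
#'   strictly increasing (possibly empty).
#' @examples
#' cpg_sites("CGCG")    # c(1, 3)
#' cpg_sites("ACGTCA")  # 2
#' @export
cpg_sites <- function(seq) {
  seq <- check_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  which(chars[-n] == "C" & chars[-1L] == "G")
}

#' In-silico bisulfite conversion of one strand
#'
#' Models complete bisulfite treatment of a single-stranded sequence.
#' Under the \code{"unmethylated"} assumption every cytosine deaminates to
#' uracil and reads as thymine after PCR, so every C becomes T. Under the
#' \code{"methylated"} assumption 5-methylcytosine at CpG sites resists
#' conversion: C in CpG context is retained, every other C becomes T.
#'
#' A cytosine at the final position has unknown CpG context (its potential G
#' partner lies outside the region); it is conservatively treated as non-CpG
#' and converted, with a warning.
#'
#' @param seq DNA string.
#' @param assumption \code{"unmethylated"} (default) or \code{"methylated"}.
#' @return converted sequence of the same length, uppercase, T-representation
#'   (no uracil).
#' @examples
#' bisulfite_convert("ACGTCA", "unmethylated")  # "ATGTTA"
#' bisulfite_convert("ACGTCA", "methylated")    # "ACGTTA"
#' @export
bisulfite_convert <- function(seq, assumption = c("unmethylated", "methylated")) {
  assumption <- match.arg(assumption)
  seq <- check_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n > 0L && chars[n] == "C") {
    warning("terminal cytosine has unknown CpG context; treated as non-CpG and converted",
            call. = FALSE)
  }
  is_c <- chars == "C"
  if (assumption == "unmethylated") {
    chars[is_c] <- "T"
  } else {
    keep <- rep(FALSE, n)
    keep[cpg_sites(seq)] <- TRUE
    chars[is_c & !keep] <- "T"
  }
  paste(chars, collapse = "")
}

#' Base composition of a sequence
#'
#' @param seq DNA string.
#' @return named integer vector with counts for A, C, G, T (summing to
#'   \code{nchar(seq)}).
#' @examples
#' base_composition("ACGT")
#' @export
base_composition <- function(seq) {
  seq <- check_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- vapply(.DNA_ALPHABET, function(b) sum(chars == b), integer(1L))
  names(counts) <- .DNA_ALPHABET
  counts
}

# ---- genomic regions and templates -------------------------------------

#' Construct a genomic region with a declared transcription start site
#'
#' A region is an uppercase A/C/G/T sequence together with the 1-based index
#' of the base numbered +1 (the TSS) in TSS-relative coordinates.
#'
#' @param name region name.
#' @param sequence DNA string.
#' @param tss_offset 1-based index of the +1 (TSS) base within the sequence.
#' @return an object of class \code{genomic_region} (list with \code{name},
#'   \code{sequence}, \code{tss_offset}).
#' @export
genomic_region <- function(name, sequence, tss_offset = 1L) {
  sequence <- check_dna(sequence, what = paste0("region '", name, "'"))
  tss_offset <- as.integer(tss_offset)
  if (is.na(tss_offset) || tss_offset < 1L || tss_offset > nchar(sequence)) {
    stop("tss_offset must lie within the sequence (1..", nchar(sequence), ")",
         call. = FALSE)
  }
  structure(list(name = as.character(name), sequence = sequence,
                 tss_offset = tss_offset),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s: %d bp, TSS(+1) at index %d, %d CpG sites\n",
              x$name, nchar(x$sequence), x$tss_offset,
              length(cpg_sites(x$sequence))))
  invisible(x)
}

#' The four single-stranded bisulfite templates of a region
#'
#' Bisulfite treatment transforms a double-stranded region into two
#' non-complementary single strands; with the methylation status unknown,
#' four template sequences are possible: \{sense, antisense\} x
#' \{methylated, unmethylated\}. Antisense templates are obtained by
#' converting the reverse complement of the region sequence.
#'
#' After conversion the strands are no longer complementary whenever the
#' region carries at least one cytosine in non-CpG context on either strand
#' (C=G pairs become T/U vs G).
#'
#' @param region a \code{\link{genomic_region}}.
#' @return a named list of four objects of class \code{bisulfite_template},
#'   names \code{"sense_methylated"}, \code{"sense_unmethylated"},
#'   \code{"antisense_methylated"}, \code{"antisense_unmethylated"}. Each
#'   holds \code{region_name}, \code{strand}, \code{assumption},
#'   \code{converted} (sequence), \code{region_length}, \code{tss_offset}.
#' @export
bisulfite_templates <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  strands <- list(sense = region$sequence,
                  antisense = reverse_complement(region$sequence))
  out <- list()
  for (st in names(strands)) {
    for (as_ in c("methylated", "unmethylated")) {
      conv <- suppressWarnings(bisulfite_convert(strands[[st]], as_))
      out[[paste(st, as_, sep = "_")]] <- structure(
        list(region_name = region$name, strand = st, assumption = as_,
             converted = conv, region_length = nchar(region$sequence),
             tss_offset = region$tss_offset),
        class = "bisulfite_template")
    }
  }
  out
}

#' @export
print.bisulfite_template <- function(x, ...) {
  cat(sprintf("<bisulfite_template> %s|%s|%s (%d bp)\n",
              x$region_name, x$strand, x$assumption, nchar(x$converted)))
  invisible(x)
}

# ---- FASTA I/O ----------------------------------------------------------

#' Read genomic regions from a FASTA file
#'
#' @param path FASTA file.
#' @param tss_offset 1-based index of the +1 base, recycled across records.
#' @return list of \code{\link{genomic_region}} objects.
#' @export
read_region_fasta <- function(path, tss_offset = 1L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  tss_offset <- rep_len(as.integer(tss_offset), length(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    nm <- sub("\\s.*$", "", names(set)[i])
    out[[i]] <- genomic_region(nm, as.character(set[[i]]), tss_offset[i])
  }
  names(out) <- vapply(out, `[[`, character(1L), "name")
  out
}

#' Write bisulfite templates to a FASTA file
#'
#' Records are named \code{"<region>|<strand>|<assumption>"}.
#'
#' @param templates list of \code{bisulfite_template} objects (as produced by
#'   \code{\link{bisulfite_templates}}).
#' @param path output FASTA file.
#' @return \code{path}, invisibly.
#' @export
write_templates_fasta <- function(templates, path) {
  seqs <- vapply(templates, `[[`, character(1L), "converted")
  nms <- vapply(templates, function(t)
    paste(t$region_name, t$strand, t$assumption, sep = "|"), character(1L))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- nms
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
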