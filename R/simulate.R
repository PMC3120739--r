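# ---- seeded synthetic data generators ----------------------------------
#
# Every generator is fully deterministic given the fixture spec's seed. One
# global seed governs all artifacts through per-artifact derived streams, so
# regions, clone sets and Ct tables can be regenerated independently yet
# reproducibly.

# Derived sub-seed per artifact; double arithmetic avoids integer overflow
# and the result stays below 2^31.
.sub_seed <- function(seed, artifact) {
  offs <- c(region = 101, clones = 211, ct = 307, fixture = 401)
  as.integer((as.numeric(seed) * 7919 + offs[[artifact]]) %% 2000000011)
}

# Run code under a local RNG stream without disturbing the caller's state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic fixture generators
#'
#' Bundles and validates every tunable of the generators. Defaults emulate
#' the study conditions of a small MethyLight calibration experiment: a
#' CpG-island-like region, clone sets with per-site Bernoulli retention and
#' conversion, and duplicate-well Ct tables with run controls.
#'
#' @param seed integer seed; mandatory, no unseeded randomness.
#' @param island_length region length in bp (default 175, an exon-1-sized
#'   fragment).
#' @param cpg_density fraction of non-overlapping dinucleotide slots that
#'   are CpG (default 0.16, CpG-island-like).
#' @param n_clones clones per sample (default 16, a typical sequencing
#'   batch).
#' @param retention_prob per-CpG probability a clone retains C
#'   (default 0.99, a fully methylated sample).
#' @param conversion_efficiency per-non-CpG-C probability of conversion to T
#'   (default 0.95).
#' @param n_pos,n_neg sample counts for Ct tables (default 20 each).
#' @param delta_ct_shift cycles separating negative from positive samples'
#'   methylation targets (default 12).
#' @param ct_noise_sd well-level Ct noise SD in cycles (default 0.3).
#' @param ct_reference_base mean reference-gene Ct (default 30).
#' @param pos_delta_ct mean target-minus-reference dCt of positive samples
#'   (default 2, i.e. RCN around 0.25).
#' @param negatives_not_detected emit negative samples' methylation target
#'   as not-detected (default TRUE, matching qualitative negatives); set
#'   FALSE for a detectable-but-late (or no-signal) design.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed,
                         island_length = 175L, cpg_density = 0.16,
                         n_clones = 16L, retention_prob = 0.99,
                         conversion_efficiency = 0.95,
                         n_pos = 20L, n_neg = 20L,
                         delta_ct_shift = 12, ct_noise_sd = 0.3,
                         ct_reference_base = 30, pos_delta_ct = 2,
                         negatives_not_detected = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  fracs <- c(cpg_density = cpg_density, retention_prob = retention_prob,
             conversion_efficiency = conversion_efficiency)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "),
         call. = FALSE)
  }
  stopifnot(island_length >= 2, n_clones >= 1, n_pos >= 1, n_neg >= 1,
            ct_noise_sd >= 0, delta_ct_shift >= 0)
  structure(list(seed = as.integer(seed),
                 island_length = as.integer(island_length),
                 cpg_density = cpg_density, n_clones = as.integer(n_clones),
                 retention_prob = retention_prob,
                 conversion_efficiency = conversion_efficiency,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 delta_ct_shift = delta_ct_shift, ct_noise_sd = ct_noise_sd,
                 ct_reference_base = ct_reference_base,
                 pos_delta_ct = pos_delta_ct,
                 negatives_not_detected = isTRUE(negatives_not_detected)),
            class = "fixture_spec")
}

#' Simulate a CpG-island-like genomic region
#'
#' The sequence is built from non-overlapping dinucleotide slots; each slot
#' is CpG with probability \code{cpg_density}, otherwise two bases drawn
#' uniformly with CG excluded (within the slot and across slot boundaries),
#' so the realized CpG count is exactly Binomial(floor(length/2), density)
#' and density 0 yields a sequence with no CG at all.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param name region name (default \code{"synthetic_island"}).
#' @param tss_offset TSS (+1) index (default 1).
#' @return a \code{\link{genomic_region}}.
#' @export
simulate_island <- function(spec, name = "synthetic_island", tss_offset = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_slots <- spec$island_length %/% 2L
  if (n_slots < 1L) stop("island_length too short", call. = FALSE)
  .with_seed(.sub_seed(spec$seed, "region"), {
    chars <- character(0)
    for (k in seq_len(n_slots)) {
      if (stats::runif(1) < spec$cpg_density) {
        slot <- c("C", "G")
      } else {
        repeat {
          first_ok <- .DNA_ALPHABET
          if (length(chars) && chars[length(chars)] == "C") {
            first_ok <- setdiff(first_ok, "G")
          }
          slot <- c(sample(first_ok, 1L), sample(.DNA_ALPHABET, 1L))
          if (!(slot[1L] == "C" && slot[2L] == "G")) break
        }
      }
      chars <- c(chars, slot)
    }
    if (spec$island_length %% 2L == 1L) {
      last_ok <- setdiff(.DNA_ALPHABET, "C")  # avoid ambiguous terminal C
      if (chars[length(chars)] == "C") last_ok <- setdiff(last_ok, "G")
      chars <- c(chars, sample(last_ok, 1L))
    }
    genomic_region(name, paste(chars, collapse = ""), tss_offset)
  })
}

#' Simulate bisulfite clone sequences from a region
#'
#' Each clone applies conversion to the region's sense strand with per-site
#' Bernoulli draws: a CpG cytosine is retained with probability
#' \code{retention_prob} (else converted to T); a non-CpG cytosine is
#' converted with probability \code{conversion_efficiency} (else retained).
#'
#' @param region a \code{\link{genomic_region}}.
#' @param spec a \code{\link{fixture_spec}}.
#' @return named character vector of clone sequences
#'   (\code{clone_01}, ...).
#' @export
simulate_clones <- function(region, spec) {
  stopifnot(inherits(region, "genomic_region"), inherits(spec, "fixture_spec"))
  sites <- classify_cytosines(region$sequence)
  base <- strsplit(region$sequence, "", fixed = TRUE)[[1L]]
  .with_seed(.sub_seed(spec$seed, "clones"), {
    clones <- vapply(seq_len(spec$n_clones), function(i) {
      cl <- base
      keep <- stats::runif(length(sites$cpg)) < spec$retention_prob
      cl[sites$cpg] <- ifelse(keep, "C", "T")
      conv <- stats::runif(length(sites$noncpg)) < spec$conversion_efficiency
      cl[sites$noncpg] <- ifelse(conv, "T", "C")
      paste(cl, collapse = "")
    }, character(1L))
    names(clones) <- sprintf("clone_%02d", seq_len(spec$n_clones))
    clones
  })
}

#' Simulate a duplicate-well MethyLight Ct table with run controls
#'
#' Reference-gene Ct is \code{ct_reference_base} plus Gaussian well noise.
#' Positive samples' methylation-target Ct sits \code{pos_delta_ct} cycles
#' above their reference Ct; negative samples are emitted as not-detected
#' (default) or shifted a further \code{delta_ct_shift} cycles. Two wells
#' per (sample, target) are emitted, plus a fully methylated positive
#' control (\code{"RKO_ctrl"}, dCt 0) and a negative control
#' (\code{"MGC803_ctrl"}, methylation target not detected).
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param target methylation target name (default \code{"p16M"}).
#' @param reference reference-gene name (default \code{"COL2A1"}).
#' @return list with \code{wells} (data.frame sample_id, target, replicate,
#'   ct), \code{labels} (data.frame sample_id, label), \code{positive_id},
#'   \code{negative_id}.
#' @export
simulate_ct_table <- function(spec, target = "p16M", reference = "COL2A1") {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(.sub_seed(spec$seed, "ct"), {
    samples <- c(sprintf("pos_%02d", seq_len(spec$n_pos)),
                 sprintf("neg_%02d", seq_len(spec$n_neg)))
    labels <- data.frame(
      sample_id = samples,
      label = rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg)))
    rows <- list()
    emit <- function(sid, tgt, ct1, ct2) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sid, target = tgt, replicate = 1:2, ct = c(ct1, ct2))
    }
    noise <- function() stats::rnorm(1, 0, spec$ct_noise_sd)
    for (i in seq_len(nrow(labels))) {
      sid <- labels$sample_id[i]
      ref_ct <- spec$ct_reference_base + noise()
      emit(sid, reference, ref_ct + noise(), ref_ct + noise())
      if (labels$label[i] == "positive") {
        tct <- ref_ct + spec$pos_delta_ct
        emit(sid, target, tct + noise(), tct + noise())
      } else if (spec$negatives_not_detected) {
        emit(sid, target, NA_real_, NA_real_)
      } else {
        tct <- ref_ct + spec$pos_delta_ct + spec$delta_ct_shift
        emit(sid, target, tct + noise(), tct + noise())
      }
    }
    # run controls
    ref_ct <- spec$ct_reference_base + noise()
    emit("RKO_ctrl", reference, ref_ct + noise(), ref_ct + noise())
    emit("RKO_ctrl", target, ref_ct + noise(), ref_ct + noise())
    ref_ct <- spec$ct_reference_base + noise()
    emit("MGC803_ctrl", reference, ref_ct + noise(), ref_ct + noise())
    emit("MGC803_ctrl", target, NA_real_, NA_real_)
    wells <- do.call(rbind, rows)
    rownames(wells) <- NULL
    list(wells = wells, labels = labels,
         positive_id = "RKO_ctrl", negative_id = "MGC803_ctrl")
  })
}

#' Build a synthetic region fixture around an assay's oligos
#'
#' Constructs a genomic region whose methylated template on the assay's
#' target strand contains the forward primer site, the probe site and the
#' reverse complement of the reverse primer site, separated by random
#' CpG-free spacers salted with non-CpG cytosines (so the unmethylated
#' template differs and the two strands are non-complementary after
#' conversion). An oligo whose written orientation is incompatible with the
#' converted template (a printed sequence carrying non-CpG cytosines, which
#' no converted methylated strand can contain) is embedded in its reverse
#' complement orientation instead; if neither orientation is compatible the
#' fixture cannot be built.
#'
#' The fixture is synthetic: it reproduces primer/probe geometry, not any
#' real locus.
#'
#' @param assay an \code{\link{assay}}.
#' @param gap_fp spacer length between forward primer and probe (default 8).
#' @param gap_pr spacer length between probe and reverse site (default 8).
#' @param flank flanking length on each side (default 25).
#' @param tss_offset TSS (+1) index of the region (default 1).
#' @param seed integer seed for the spacers.
#' @param name region name.
#' @return a \code{\link{genomic_region}}; attribute
#'   \code{"expected_template_span"} holds the constructed amplicon's
#'   template start/end on the target strand.
#' @export
build_assay_fixture <- function(assay, gap_fp = 8L, gap_pr = 8L, flank = 25L,
                                tss_offset = 1L, seed = 1L,
                                name = paste0(assay$name, "_synthetic_fixture")) {
  stopifnot(inherits(assay, "assay"))
  # a sequence is a valid methylated-template segment iff all its C are CpG
  valid_site <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    cs <- which(chars == "C")
    all(cs %in% cpg_sites(s)) && chars[length(chars)] != "C"
  }
  site_for <- function(oligo, want_revcomp = FALSE) {
    s <- if (want_revcomp) reverse_complement(oligo$sequence) else oligo$sequence
    if (valid_site(s)) return(s)
    s2 <- if (want_revcomp) oligo$sequence else reverse_complement(oligo$sequence)
    if (valid_site(s2)) return(s2)
    stop("oligo ", oligo$name,
         " cannot be embedded in a converted methylated template in either orientation",
         call. = FALSE)
  }
  f_site <- site_for(assay$forward, want_revcomp = FALSE)
  p_site <- site_for(assay$probe, want_revcomp = FALSE)
  r_site <- site_for(assay$reverse, want_revcomp = TRUE)
  # Spacers draw from {A,T,C} only (no G, so no CpG can arise inside or at a
  # junction) and never end in C, keeping site/spacer boundaries clean; the
  # C's are conversion-sensitive, which makes the U template differ from the
  # M template outside the oligo sites too.
  spacer <- function(n) {
    if (n == 0L) return("")
    chars <- vapply(seq_len(n), function(i) {
      sample(if (i == n) c("A", "T") else c("A", "T", "C"), 1L)
    }, character(1L))
    paste(chars, collapse = "")
  }
  .with_seed(.sub_seed(seed, "fixture"), {
    left <- spacer(flank)
    g1 <- spacer(gap_fp)
    g2 <- spacer(gap_pr)
    right <- spacer(flank)
    target_seg <- paste0(left, f_site, g1, p_site, g2, r_site, right)
    genome <- if (assay$target_strand == "sense") target_seg
              else reverse_complement(target_seg)
    region <- genomic_region(name, genome, tss_offset)
    t_start <- flank + 1L
    t_end <- flank + nchar(f_site) + gap_fp + nchar(p_site) + gap_pr +
      nchar(r_site)
    attr(region, "expected_template_span") <- c(start = t_start, end = t_end)
    region
  })
}

#' Write a complete fixture set to a directory
#'
#' Generates a region, its clone set, and a Ct table with labels, written as
#' \code{region.fa}, \code{clones.fa}, \code{ct.tsv} and \code{labels.tsv}.
#' Byte-identical across runs for the same spec.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixture_set <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  region <- simulate_island(spec)
  clones <- simulate_clones(region, spec)
  ct <- simulate_ct_table(spec)
  paths <- file.path(outdir, c("region.fa", "clones.fa", "ct.tsv", "labels.tsv"))
  reg_set <- Biostrings::DNAStringSet(stats::setNames(region$sequence, region$name))
  Biostrings::writeXStringSet(reg_set, paths[1L])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(clones), paths[2L])
  ct_out <- ct$wells
  ct_out$ct <- ifelse(is.na(ct_out$ct), "ND", format(ct_out$ct, digits = 10))
  utils::write.table(ct_out, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct$labels, paths[4L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
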