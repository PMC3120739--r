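# Shared fixture builders and independent oracles. Everything is generated
# in code under explicit seeds; no binary fixtures.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Naive quadratic CpG scan: independent oracle for cpg_sites().
naive_cpg_scan <- function(seq) {
  out <- integer(0)
  for (p in seq_len(max(nchar(seq) - 1L, 0L))) {
    if (substr(seq, p, p + 1L) == "CG") out <- c(out, p)
  }
  out
}

# Build a conversion-insensitive (C-free template) assay plus its region,
# with known primer geometry: forward starts at f_pos, reverse 5' end at
# r5_pos, both on the sense strand. Returns the pieces and the expected
# inclusive amplicon length.
make_neutral_fixture <- function(seed, flank = 10L, f_len = 20L, gap1 = 8L,
                                 p_len = 18L, gap2 = 7L, r_len = 19L) {
  set.seed(seed)
  agt <- c("A", "G", "T")
  f_site <- rand_dna(f_len, agt)
  p_site <- rand_dna(p_len, agt)
  r_site <- rand_dna(r_len, agt)
  genome <- paste0(rand_dna(flank, agt), f_site, rand_dna(gap1, agt),
                   p_site, rand_dna(gap2, agt), r_site, rand_dna(flank, agt))
  asy <- suppressWarnings(assay(
    name = sprintf("neutral_%d", seed),
    forward = parse_oligo(f_site, "forward", "synF"),
    reverse = parse_oligo(reverse_complement(r_site), "reverse", "synR"),
    probe = parse_oligo(p_site, "probe", "synP"),
    target_strand = "sense", reference = TRUE))
  f_pos <- flank + 1L
  r5_pos <- flank + f_len + gap1 + p_len + gap2 + r_len
  list(assay = asy, region = genomic_region("neutral_region", genome),
       f_pos = f_pos, r5_pos = r5_pos,
       expected_len = r5_pos - f_pos + 1L)
}

# Reference strand with exactly 14 CpG cytosines and 44 non-CpG cytosines
# per clone (the per-clone site structure of a fully methylated bisulfite
# sequencing experiment).
make_clone_reference <- function(n_cpg = 14L, n_noncpg = 44L) {
  paste0(strrep("ACGT", n_cpg), strrep("CA", n_noncpg), "TT")
}

# Build a clone set from a reference with exact pooled counts: n_retained of
# the CpG cytosines kept (pooled over clones, filled clone by clone) and
# n_converted of the non-CpG cytosines converted.
make_counted_clones <- function(reference, n_clones, n_retained, n_converted) {
  sites <- classify_cytosines(reference)
  base <- strsplit(reference, "", fixed = TRUE)[[1L]]
  total_cpg <- length(sites$cpg) * n_clones
  total_non <- length(sites$noncpg) * n_clones
  stopifnot(n_retained <= total_cpg, n_converted <= total_non)
  keep_flags <- rep(c(TRUE, FALSE), c(n_retained, total_cpg - n_retained))
  conv_flags <- rep(c(TRUE, FALSE), c(n_converted, total_non - n_converted))
  clones <- character(n_clones)
  for (i in seq_len(n_clones)) {
    cl <- base
    k <- keep_flags[((i - 1L) * length(sites$cpg) + 1L):(i * length(sites$cpg))]
    cl[sites$cpg] <- ifelse(k, "C", "T")
    cv <- conv_flags[((i - 1L) * length(sites$noncpg) + 1L):(i * length(sites$noncpg))]
    cl[sites$noncpg] <- ifelse(cv, "T", "C")
    clones[i] <- paste(cl, collapse = "")
  }
  clones
}

# Brute-force ROC oracle: enumerate every achievable (sensitivity,
# specificity) pair under the rule score >= cutoff, over all candidate
# cutoffs (0, all midpoints, every observed score, Inf).
brute_force_roc <- function(scores, labels, positive = "positive") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cand <- sort(unique(c(0, scores, Inf,
                        (sort(scores)[-1] + sort(scores)[-length(scores)]) / 2)))
  pts <- unique(t(vapply(cand, function(c)
    c(sens = mean(pos >= c), spec = mean(neg < c)), numeric(2L))))
  pts[order(pts[, "sens"], pts[, "spec"]), , drop = FALSE]
}

# Pairwise Mann-Whitney AUC oracle (ties counted half).
mann_whitney_auc <- function(scores, labels, positive = "positive") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Exhaustive Youden oracle: best sensitivity + specificity - 1 achievable.
exhaustive_youden <- function(scores, labels, positive = "positive") {
  pts <- brute_force_roc(scores, labels, positive)
  max(pts[, "sens"] + pts[, "spec"] - 1)
}

# Minimal well-table builder for quantification tests.
make_wells <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1L]], target = r[[2L]],
               replicate = as.integer(r[[3L]]),
               ct = if (is.na(r[[4L]])) NA_real_ else as.numeric(r[[4L]]))))
}
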