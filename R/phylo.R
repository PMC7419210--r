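## Distance phylogenetics: Kimura two-parameter distances with
## delta-method standard errors, neighbor-joining with deterministic
## tie-breaks, column-bootstrap supports, the Tajima relative rate test
## and substitution-rate duplication timing.

#' Kimura two-parameter distance between two aligned sequences
#'
#' With transition proportion `P` and transversion proportion `Q` over the
#' comparable (both-ACGT) sites, `K = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`.
#' The standard error comes from the usual delta-method variance. Pairs
#' with `1 - 2P - Q <= 0` or `1 - 2Q <= 0` are flagged saturated
#' (`K = NA`).
#'
#' @param seq1,seq2 Aligned nucleotide strings of equal length.
#' @return Named list: `K`, `se`, `P`, `Q`, `n_sites`, `saturated`.
#' @examples
#' # P = 0.1, Q = 0.05 gives K = 0.1702
#' @export
k2p_distance <- function(seq1, seq2) {
  b1 <- strsplit(toupper(seq1), "")[[1]]
  b2 <- strsplit(toupper(seq2), "")[[1]]
  stopifnot(length(b1) == length(b2))
  ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
  b1 <- b1[ok]; b2 <- b2[ok]
  n <- length(b1)
  if (n < 1) abort("no comparable sites after gap handling")
  diff <- b1 != b2
  P <- sum(diff & is_transition(b1, b2)) / n
  Q <- sum(diff & !is_transition(b1, b2)) / n
  k2p_from_pq(P, Q, n)
}

k2p_from_pq <- function(P, Q, n) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    return(list(K = NA_real_, se = NA_real_, P = P, Q = Q,
                n_sites = n, saturated = TRUE))
  }
  K <- -0.5 * log(a1) - 0.25 * log(a2)
  c1 <- 1 / a1
  c2 <- 1 / a2
  c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  list(K = K, se = sqrt(v), P = P, Q = Q, n_sites = n, saturated = FALSE)
}

#' K2P distance matrix of an alignment
#'
#' @param sequences Named character vector of aligned sequences.
#' @return Symmetric numeric matrix of K2P distances with an `se` matrix
#'   attribute; saturated pairs are `NA`.
#' @export
k2p_matrix <- function(sequences) {
  labs <- names(sequences)
  stopifnot(!is.null(labs), length(sequences) >= 2)
  n <- length(sequences)
  K <- matrix(0, n, n, dimnames = list(labs, labs))
  SE <- K
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- k2p_distance(sequences[[i]], sequences[[j]])
      K[i, j] <- K[j, i] <- d$K
      SE[i, j] <- SE[j, i] <- d$se
    }
  }
  attr(K, "se") <- SE
  K
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration on the Q criterion with standard NJ
#' branch lengths. Ties in Q are broken deterministically by the
#' lexicographically lowest pair of cluster representative labels (the
#' smallest original taxon label in each cluster). Negative branch
#' lengths are clamped to zero and counted in the `clamped` attribute.
#' Applied to an additive (tree-like) matrix, NJ recovers the generating
#' topology and branch lengths exactly.
#'
#' @param dm Symmetric distance matrix with dimnames (or a `dist`).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) >= 3, !is.null(rownames(dm)))
  if (any(!is.finite(dm))) {
    bad <- which(!is.finite(dm) & upper.tri(dm), arr.ind = TRUE)
    abort(paste0("non-finite (saturated?) distances for pair(s): ",
                 paste(sprintf("%s-%s", rownames(dm)[bad[, 1]],
                               colnames(dm)[bad[, 2]]), collapse = ", ")))
  }
  labs <- rownames(dm)
  newick <- labs        # newick fragment per active node
  rep_lab <- labs       # representative label for tie-breaking
  D <- dm
  clamped <- 0L
  clamp <- function(v) {
    if (v < 0) { clamped <<- clamped + 1L; 0 } else v
  }
  while (nrow(D) > 3) {
    r <- nrow(D)
    Rsum <- rowSums(D)
    Q <- (r - 2) * D - outer(Rsum, Rsum, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-9 * max(1, abs(qmin)) & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      key <- vapply(seq_len(nrow(cand)), function(k) {
        paste(sort(c(rep_lab[cand[k, 1]], rep_lab[cand[k, 2]])), collapse = "\r")
      }, character(1))
      cand <- cand[order(key)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- clamp(D[i, j] / 2 + (Rsum[i] - Rsum[j]) / (2 * (r - 2)))
    vj <- clamp(D[i, j] - (D[i, j] / 2 + (Rsum[i] - Rsum[j]) / (2 * (r - 2))))
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], vi, newick[j], vj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    newick <- c(newick[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    dimnames(D) <- NULL
  }
  va <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 newick[1], va, newick[2], vb, newick[3], vc)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  if (clamped > 0) warn(sprintf("%d negative NJ branch length(s) clamped to 0", clamped))
  tree
}

#' Bootstrap supports for the K2P/NJ tree of an alignment
#'
#' Builds the full-data K2P + NJ tree, then resamples alignment columns
#' with replacement `n_replicates` times, rebuilds the tree each time, and
#' attaches to each internal bipartition of the full-data tree the
#' fraction of replicate trees containing it (`node.label`). Replicates
#' with saturated distances are dropped and counted. Deterministic under a
#' fixed seed.
#'
#' @param sequences Named character vector of aligned sequences (>= 4).
#' @param n_replicates Bootstrap replicates (the study-scale default 500).
#' @param seed Integer seed.
#' @return The full-data `phylo` with `node.label` supports in `[0, 1]`
#'   and attributes `n_replicates`, `n_used`.
#' @export
bootstrap_support <- function(sequences, n_replicates = 500, seed = 1) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  stopifnot(length(sequences) >= 4)
  set.seed(as.integer(seed))
  mat <- do.call(rbind, strsplit(toupper(unlist(sequences)), ""))
  rownames(mat) <- names(sequences)
  ncol_aln <- ncol(mat)
  if (ncol_aln < 1) abort("alignment has no columns")
  full <- nj_tree(k2p_matrix(sequences))
  reps <- list()
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    sub <- apply(mat[, cols, drop = FALSE], 1, paste0, collapse = "")
    K <- k2p_matrix(sub)
    if (any(is.na(K))) next
    reps[[length(reps) + 1]] <- suppressWarnings(nj_tree(K))
  }
  n_used <- length(reps)
  if (n_used == 0) abort("all bootstrap replicates were saturated")
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- counts / n_used
  attr(full, "n_replicates") <- n_replicates
  attr(full, "n_used") <- n_used
  full
}

#' Tajima relative rate test
#'
#' For three aligned sequences A, B and an outgroup, counts the sites
#' where only A differs (`m1`: B equals the outgroup) and where only B
#' differs (`m2`), and tests rate equality with
#' `chi2 = (m1 - m2)^2 / (m1 + m2)` on one degree of freedom. With
#' `m1 + m2 = 0` the test is undefined and flagged.
#'
#' @param seqA,seqB,outgroup Aligned nucleotide strings of equal length.
#' @return One-row tibble: `m1`, `m2`, `chi2`, `p`, `undefined`.
#' @export
tajima_rrt <- function(seqA, seqB, outgroup) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  o <- strsplit(toupper(outgroup), "")[[1]]
  if (length(a) != length(b) || length(a) != length(o)) {
    abort("sequences must have equal length")
  }
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T") &
    o %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]; o <- o[ok]
  m1 <- sum(a != b & b == o)
  m2 <- sum(a != b & a == o)
  if (m1 + m2 == 0) {
    return(tibble(m1 = m1, m2 = m2, chi2 = NA_real_, p = NA_real_, undefined = TRUE))
  }
  chi2 <- (m1 - m2)^2 / (m1 + m2)
  tibble(m1 = m1, m2 = m2, chi2 = chi2,
         p = pchisq(chi2, df = 1, lower.tail = FALSE), undefined = FALSE)
}

#' Calibrate a substitution rate from a dated divergence
#'
#' `R = K / (2T)`: `K` substitutions per site between two lineages that
#' split `T` million years ago gives the per-lineage rate in
#' substitutions/site/My. Canonical calibration points: chimpanzee-human
#' 6-7 Mya, orangutan 15, macaque 25, Old World/New World monkey split 35.
#'
#' @param K Pairwise distance (substitutions per site, >= 0).
#' @param T_mya Divergence time in millions of years (> 0).
#' @return Rate in substitutions/site/My.
#' @export
calibrate_rate <- function(K, T_mya) {
  if (any(K < 0)) abort("K must be >= 0")
  if (any(T_mya <= 0)) abort("T must be > 0")
  K / (2 * T_mya)
}

#' Date a duplication from a distance and a calibrated rate
#'
#' `T = K / (2R)`; inverse of [calibrate_rate()], so
#' `duplication_time(K, calibrate_rate(K, T)) == T`.
#'
#' @param K Pairwise distance between the duplicate copies (>= 0).
#' @param rate Substitution rate per site per My (> 0).
#' @return Time in millions of years.
#' @export
duplication_time <- function(K, rate) {
  if (any(K < 0)) abort("K must be >= 0")
  if (any(rate <= 0)) abort("rate must be > 0")
  K / (2 * rate)
}
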