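## Codon-level selection statistics: modified Nei-Gojobori counting with
## transition/transversion-weighted potential sites, pathway averaging for
## multi-difference codons, and the one-tailed D = dN - dS Z-test.

CODON_BASES <- c("T", "C", "A", "G")

# standard genetic code, positions ordered T,C,A,G with third base fastest
GENETIC_CODE_STR <-
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

codon_table <- function() {
  if (is.null(.dupliconevo_cache$codons)) {
    grid <- expand.grid(p3 = CODON_BASES, p2 = CODON_BASES, p1 = CODON_BASES,
                        stringsAsFactors = FALSE)
    codons <- paste0(grid$p1, grid$p2, grid$p3)
    aa <- strsplit(GENETIC_CODE_STR, "")[[1]]
    .dupliconevo_cache$codons <- setNames(aa, codons)
  }
  .dupliconevo_cache$codons
}

#' All 61 sense codons
#' @return Character vector of the sense (non-stop) codons.
#' @export
sense_codons <- function() {
  tab <- codon_table()
  names(tab)[tab != "*"]
}

translate_codon <- function(codon) unname(codon_table()[codon])

is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Potential synonymous and nonsynonymous sites of a codon
#'
#' Each codon position distributes one site across its three single-base
#' changes. With ts/tv ratio `R`, the transition carries weight
#' `R / (R + 1)` and each transversion `(1 / (R + 1)) / 2`; `R = 0.5`
#' weighs all three changes equally (the original, unweighted method).
#' Changes to stop codons are removed and the remaining weights
#' renormalized per position, so `n_nonsyn + n_syn = 3` for every sense
#' codon.
#'
#' @param codon Three-letter ACGT codon (not a stop).
#' @param ts_tv_ratio Transition/transversion ratio `R` (> 0) used in the
#'   site weighting; default 0.5.
#' @return Named numeric vector `c(n_nonsyn, n_syn)`.
#' @examples
#' potential_sites("TTT") # c(8/3, 1/3)
#' @export
potential_sites <- function(codon, ts_tv_ratio = 0.5) {
  stopifnot(ts_tv_ratio > 0)
  tab <- codon_table()
  codon <- toupper(codon)
  if (is.na(tab[codon])) abort(sprintf("invalid codon: %s", codon))
  if (tab[codon] == "*") abort("potential_sites is undefined for stop codons")
  aa0 <- tab[[codon]]
  bases <- strsplit(codon, "")[[1]]
  w_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
  w_tv <- (1 - w_ts) / 2
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(CODON_BASES, bases[pos])
    w <- ifelse(is_transition(bases[pos], alts), w_ts, w_tv)
    neigh <- vapply(alts, function(b) {
      nb <- bases; nb[pos] <- b; paste0(nb, collapse = "")
    }, character(1))
    aa <- tab[neigh]
    keep <- aa != "*"
    if (!any(keep)) next # position contributes nothing if all paths hit stops
    w <- w[keep] / sum(w[keep])
    s <- s + sum(w[aa[keep] == aa0])
  }
  c(n_nonsyn = 3 - s, n_syn = s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Zero-difference pairs give `(0, 0)`; single differences are classified
#' directly; two- and three-difference pairs average, with equal weight,
#' over all orderings of the single-base steps, excluding any pathway
#' passing through a stop codon. If every pathway is blocked by stops the
#' pair is unresolvable and `(NA, NA)` is returned (callers skip and flag
#' such codons).
#'
#' @param codon1,codon2 Three-letter ACGT sense codons.
#' @return Named numeric vector `c(Nd, Sd)`.
#' @examples
#' pairwise_differences("TTT", "GTA") # c(1.5, 0.5)
#' @export
pairwise_differences <- function(codon1, codon2) {
  tab <- codon_table()
  codon1 <- toupper(codon1); codon2 <- toupper(codon2)
  for (cd in c(codon1, codon2)) {
    if (is.na(tab[cd])) abort(sprintf("invalid codon: %s", cd))
    if (tab[cd] == "*") abort("pairwise_differences is undefined for stop codons")
  }
  b1 <- strsplit(codon1, "")[[1]]
  b2 <- strsplit(codon2, "")[[1]]
  diffpos <- which(b1 != b2)
  if (length(diffpos) == 0) return(c(Nd = 0, Sd = 0))
  orders <- perms(diffpos)
  acc_n <- 0; acc_s <- 0; n_valid <- 0
  for (ord in orders) {
    cur <- b1; nd <- 0; sd_ <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b2[pos]
      cn <- paste0(cur, collapse = ""); nn <- paste0(nxt, collapse = "")
      if (tab[[nn]] == "*") { ok <- FALSE; break }
      if (tab[[cn]] == tab[[nn]]) sd_ <- sd_ + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { acc_n <- acc_n + nd; acc_s <- acc_s + sd_; n_valid <- n_valid + 1 }
  }
  if (n_valid == 0) return(c(Nd = NA_real_, Sd = NA_real_))
  c(Nd = acc_n / n_valid, Sd = acc_s / n_valid)
}

perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# memoised lookup tables keyed by the ts/tv ratio
sites_table <- function(ts_tv_ratio) {
  key <- paste0("sites_", format(ts_tv_ratio, digits = 12))
  if (is.null(.dupliconevo_cache[[key]])) {
    sc <- sense_codons()
    m <- t(vapply(sc, potential_sites, numeric(2), ts_tv_ratio = ts_tv_ratio))
    .dupliconevo_cache[[key]] <- m
  }
  .dupliconevo_cache[[key]]
}

diffs_table <- function() {
  if (is.null(.dupliconevo_cache$diffs)) {
    sc <- sense_codons()
    n <- length(sc)
    Nd <- matrix(NA_real_, n, n, dimnames = list(sc, sc))
    Sd <- Nd
    for (i in seq_len(n)) {
      for (j in i:n) {
        d <- pairwise_differences(sc[i], sc[j])
        Nd[i, j] <- Nd[j, i] <- d[["Nd"]]
        Sd[i, j] <- Sd[j, i] <- d[["Sd"]]
      }
    }
    .dupliconevo_cache$diffs <- list(Nd = Nd, Sd = Sd)
  }
  .dupliconevo_cache$diffs
}

split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  n <- nchar(seq)
  if (n %% 3 != 0) abort("sequence length is not a multiple of 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Pairwise dN/dS by the modified Nei-Gojobori method
#'
#' Counts pathway-averaged synonymous and nonsynonymous differences and
#' ts/tv-weighted potential sites over the comparable codons of an aligned
#' pair, estimates per-site rates with either the proportion (`d = p`) or
#' Jukes-Cantor (`d = -3/4 log(1 - 4p/3)`) correction, and tests
#' `D = dN - dS` with a one-tailed Z-test, `Z = D / sigma`,
#' `sigma = sqrt(var_dN + var_dS)` from the large-sample binomial
#' (delta-method) variances matched to the correction. The default
#' direction tests for positive selection (`dN > dS`).
#'
#' @param seq1,seq2 Aligned in-frame nucleotide strings of equal length.
#' @param ts_tv_ratio Ts/tv ratio for the potential-site weighting
#'   (0.5 = unweighted/original method).
#' @param correction `"jukes_cantor"` (default) or `"proportion"`.
#' @param direction `"positive"` tests dN > dS, `"purifying"` dS > dN.
#' @param labels Length-2 labels for the pair.
#' @return One-row tibble of class `dnds_pair`: `label1`, `label2`,
#'   `n_codons` (compared), `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`, `pS`,
#'   `dN`, `dS`, `var_dN`, `var_dS`, `D`, `Z`, `p`, `saturated`,
#'   `n_skipped` (gap/ambiguous/stop/unresolvable codons dropped).
#' @export
dn_ds <- function(seq1, seq2, ts_tv_ratio = 0.5,
                  correction = c("jukes_cantor", "proportion"),
                  direction = c("positive", "purifying"),
                  labels = c("seq1", "seq2")) {
  correction <- match.arg(correction)
  direction <- match.arg(direction)
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  stopifnot(length(c1) == length(c2))
  tab <- codon_table()
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  clean[clean] <- tab[c1[clean]] != "*" & tab[c2[clean]] != "*"
  n_skipped <- sum(!clean)
  c1 <- c1[clean]; c2 <- c2[clean]
  if (length(c1) == 0) abort("no comparable codons after gap/stop handling")
  st <- sites_table(ts_tv_ratio)
  dt <- diffs_table()
  Nd_i <- dt$Nd[cbind(c1, c2)]
  unres <- is.na(Nd_i)
  if (any(unres)) {
    warn(sprintf("%d codon pair(s) unresolvable (all pathways through stops); skipped",
                 sum(unres)))
    n_skipped <- n_skipped + sum(unres)
    c1 <- c1[!unres]; c2 <- c2[!unres]
  }
  Nd <- sum(dt$Nd[cbind(c1, c2)])
  Sd <- sum(dt$Sd[cbind(c1, c2)])
  N <- (sum(st[c1, "n_nonsyn"]) + sum(st[c2, "n_nonsyn"])) / 2
  S <- (sum(st[c1, "n_syn"]) + sum(st[c2, "n_syn"])) / 2
  pN <- Nd / N
  pS <- Sd / S
  corr <- function(p, L) {
    if (correction == "proportion") {
      # p can exceed 1 when pathway-averaged counts outnumber potential
      # sites; the binomial variance is then meaningless
      if (p > 1) list(d = p, v = NA_real_, sat = TRUE)
      else list(d = p, v = p * (1 - p) / L, sat = FALSE)
    } else if (p >= 0.75) {
      list(d = NA_real_, v = NA_real_, sat = TRUE)
    } else {
      list(d = -3 / 4 * log(1 - 4 * p / 3),
           v = p * (1 - p) / (L * (1 - 4 * p / 3)^2), sat = FALSE)
    }
  }
  cn <- corr(pN, N); cs <- corr(pS, S)
  D <- cn$d - cs$d
  sigma <- sqrt(cn$v + cs$v)
  Z <- if (!is.na(D) && !is.na(sigma) && sigma > 0) D / sigma
  else if (!is.na(D) && D == 0) 0 else NA_real_
  if (direction == "purifying" && !is.na(Z)) Z <- -Z
  p <- if (is.na(Z)) NA_real_ else pnorm(Z, lower.tail = FALSE)
  out <- tibble(label1 = labels[1], label2 = labels[2],
                n_codons = length(c1), N_sites = N, S_sites = S,
                Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                dN = cn$d, dS = cs$d, var_dN = cn$v, var_dS = cs$v,
                D = D, Z = Z, p = p,
                saturated = cn$sat || cs$sat, n_skipped = n_skipped)
  attr(out, "ts_tv_ratio") <- ts_tv_ratio
  attr(out, "correction") <- correction
  attr(out, "direction") <- direction
  class(out) <- c("dnds_pair", class(out))
  out
}

#' @method tidy dnds_pair
#' @export
tidy.dnds_pair <- function(x, ...) as_tibble(x)

#' @method glance dnds_pair
#' @export
glance.dnds_pair <- function(x, ...) {
  tibble(correction = attr(x, "correction"),
         ts_tv_ratio = attr(x, "ts_tv_ratio"),
         direction = attr(x, "direction"))
}

#' Per-group, per-exon selection scan
#'
#' Runs every within-group pairwise [dn_ds()] on each exon's codon range
#' and summarises per (group x exon): mean dN, dS and D over pairs, the
#' mean pairwise Z, and a pooled test in which the difference and
#' nonsynonymous/synonymous counts are summed over pairs before the
#' correction and Z-test (pairs within a group share history, so the
#' pooled Z treats the summed counts as one large comparison). Excluded
#' exons (by default the C-terminal repeat-array exon `"exon8"`, whose
#' global alignment is unreliable) are absent from the output; groups with
#' fewer than two members are skipped with a warning.
#'
#' @param sequences Named character vector of aligned in-frame sequences,
#'   or a tibble with columns `label`, `seq`.
#' @param groups Named character vector or tibble (`label`, `group`)
#'   assigning each sequence to a paralog group (e.g. HSA, GGO, PTR, PPY,
#'   OWM, CJA).
#' @param exon_partition Tibble with columns `exon`, `start_codon`,
#'   `end_codon` (1-based, inclusive codon indices); `NULL` treats the
#'   whole alignment as one exon `"all"`.
#' @param exclude_exons Exon labels to omit.
#' @inheritParams dn_ds
#' @param alpha Significance level for the pooled one-tailed test.
#' @return Tibble of class `selection_scan`, one row per (group, exon):
#'   `group`, `exon`, `n_seqs`, `n_pairs`, `mean_dN`, `mean_dS`, `mean_D`,
#'   `mean_Z`, `pooled_dN`, `pooled_dS`, `pooled_D`, `pooled_Z`,
#'   `pooled_p`, `significant`.
#' @export
group_selection_scan <- function(sequences, groups, exon_partition = NULL,
                                 exclude_exons = "exon8",
                                 ts_tv_ratio = 0.5,
                                 correction = c("jukes_cantor", "proportion"),
                                 direction = c("positive", "purifying"),
                                 alpha = 0.05) {
  correction <- match.arg(correction)
  direction <- match.arg(direction)
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$seq, sequences$label)
  }
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$label)
  stopifnot(all(names(sequences) %in% names(groups)) || all(names(groups) %in% names(sequences)))
  n_codons <- nchar(sequences[[1]]) / 3
  if (is.null(exon_partition)) {
    exon_partition <- tibble(exon = "all", start_codon = 1, end_codon = n_codons)
  }
  exon_partition <- exon_partition[!exon_partition$exon %in% exclude_exons, , drop = FALSE]
  stopifnot(all(exon_partition$start_codon >= 1),
            all(exon_partition$end_codon <= n_codons))
  rows <- list()
  for (g in unique(groups[names(sequences)])) {
    members <- names(sequences)[groups[names(sequences)] == g]
    if (length(members) < 2) {
      warn(sprintf("group %s has fewer than 2 sequences; skipped", g))
      next
    }
    prs <- utils::combn(members, 2, simplify = FALSE)
    for (e in seq_len(nrow(exon_partition))) {
      from <- (exon_partition$start_codon[e] - 1) * 3 + 1
      to <- exon_partition$end_codon[e] * 3
      pair_res <- map(prs, function(pr) {
        dn_ds(substr(sequences[[pr[1]]], from, to),
              substr(sequences[[pr[2]]], from, to),
              ts_tv_ratio = ts_tv_ratio, correction = correction,
              direction = direction, labels = pr)
      }) |> list_rbind()
      pooled_pN <- sum(pair_res$Nd) / sum(pair_res$N_sites)
      pooled_pS <- sum(pair_res$Sd) / sum(pair_res$S_sites)
      # pairs within a group share branches: every lineage enters m - 1 of
      # the m(m-1)/2 pairwise comparisons, so the variance of the pooled
      # counts exceeds the naive binomial one by about (m - 1); deflate the
      # effective site totals accordingly before the Z-test
      eff <- length(members) - 1
      pool <- pooled_test(pooled_pN, pooled_pS, sum(pair_res$N_sites) / eff,
                          sum(pair_res$S_sites) / eff, correction, direction)
      rows[[length(rows) + 1]] <- tibble(
        group = g, exon = exon_partition$exon[e],
        n_seqs = length(members), n_pairs = length(prs),
        mean_dN = mean(pair_res$dN), mean_dS = mean(pair_res$dS),
        mean_D = mean(pair_res$D), mean_Z = mean(pair_res$Z),
        pooled_dN = pool$dN, pooled_dS = pool$dS, pooled_D = pool$D,
        pooled_Z = pool$Z, pooled_p = pool$p,
        significant = !is.na(pool$p) && pool$p < alpha)
    }
  }
  out <- list_rbind(rows)
  attr(out, "correction") <- correction
  attr(out, "ts_tv_ratio") <- ts_tv_ratio
  attr(out, "alpha") <- alpha
  class(out) <- c("selection_scan", class(out))
  out
}

pooled_test <- function(pN, pS, N, S, correction, direction) {
  corr <- function(p, L) {
    if (correction == "proportion") list(d = p, v = p * (1 - p) / L)
    else if (p >= 0.75) list(d = NA_real_, v = NA_real_)
    else list(d = -3 / 4 * log(1 - 4 * p / 3),
              v = p * (1 - p) / (L * (1 - 4 * p / 3)^2))
  }
  cn <- corr(pN, N); cs <- corr(pS, S)
  D <- cn$d - cs$d
  sigma <- sqrt(cn$v + cs$v)
  Z <- if (!is.na(D) && !is.na(sigma) && sigma > 0) D / sigma
  else if (!is.na(D) && D == 0) 0 else NA_real_
  if (direction == "purifying" && !is.na(Z)) Z <- -Z
  list(dN = cn$d, dS = cs$d, D = D, Z = Z,
       p = if (is.na(Z)) NA_real_ else pnorm(Z, lower.tail = FALSE))
}

#' @method tidy selection_scan
#' @export
tidy.selection_scan <- function(x, ...) as_tibble(x)

#' @method glance selection_scan
#' @export
glance.selection_scan <- function(x, ...) {
  tibble(correction = attr(x, "correction"),
         ts_tv_ratio = attr(x, "ts_tv_ratio"),
         alpha = attr(x, "alpha"),
         n_significant = sum(x$significant))
}

#' Plot a selection scan
#'
#' @param object A `selection_scan`.
#' @param ... Unused.
#' @return A ggplot of pooled D per (exon, group), significant cells marked.
#' @method autoplot selection_scan
#' @export
autoplot.selection_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$exon, y = .data$pooled_D,
                                       fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(y = "pooled D = dN - dS", x = NULL,
                  fill = sprintf("one-tailed p < %s", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}
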