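## Seeded desk-scale generators with known ground truth: a repeat-annotated
## genome landscape with GC heterogeneity and GC-coupled SINE density, a
## duplication history with planted donor enrichment, Alu-seeded junctions
## and lognormal pre-integration deletions, and codon paralog families
## evolved under per-group omega with ts/tv bias kappa.

#' Simulate a repeat-annotated genome landscape
#'
#' Chromosomes carry a blockwise GC track (block GC ~ Normal(`gc_base`,
#' `gc_block_sd`), truncated to (0.05, 0.95)). SINEs are placed by a
#' Poisson process whose per-block intensity carries a
#' `sine_gc_coupling`-fold odds multiplier in high-GC blocks (block GC
#' above `gc_base`), renormalized so the genome-wide mean density equals
#' `sine_density`; LINEs and LTRs are homogeneous. An exclusion mask (the
#' stand-in for SDs, centromeres, telomeres and gaps) covers about
#' `exclusion_fraction` of each chromosome.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome.
#' @param gc_base,gc_block_sd Mean and between-block SD of GC fraction.
#' @param gc_block_bp GC block size.
#' @param sine_density,line_density,ltr_density Elements per Mbp.
#' @param sine_gc_coupling Odds multiplier for SINE placement in high-GC
#'   blocks (1 = no coupling).
#' @param exclusion_fraction Target masked fraction per chromosome.
#' @param sine_len,line_len,ltr_len Fixed element lengths (bp).
#' @param seed Integer seed.
#' @return List with `landscape` (a [genome_landscape()]) and `truth`
#'   (the generating parameters plus the per-block SINE intensities).
#' @export
simulate_landscape <- function(n_chroms = 8, chrom_length_bp = 12e6,
                               gc_base = 0.41, gc_block_sd = 0.05,
                               gc_block_bp = 5e5,
                               sine_density = 300, line_density = 60,
                               ltr_density = 0,
                               sine_gc_coupling = 4,
                               exclusion_fraction = 0.1,
                               sine_len = 300, line_len = 6000, ltr_len = 500,
                               seed = 1) {
  stopifnot(sine_density >= 0, line_density >= 0, ltr_density >= 0,
            gc_base > 0, gc_base < 1, exclusion_fraction >= 0,
            exclusion_fraction < 1, sine_gc_coupling > 0)
  exp_bases <- (sine_density * sine_len + line_density * line_len +
                  ltr_density * ltr_len) / 1e6
  if (exp_bases > 0.5) {
    abort("infeasible repeat density: expected element coverage exceeds half the genome")
  }
  set.seed(as.integer(seed))
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  sizes <- tibble(chrom = chroms, size = chrom_length_bp)

  blocks <- purrr::map(chroms, function(ch) {
    starts <- seq(0, chrom_length_bp - 1, by = gc_block_bp)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + gc_block_bp, chrom_length_bp))
  }) |> list_rbind()
  blocks$gc <- pmin(0.95, pmax(0.05, rnorm(nrow(blocks), gc_base, gc_block_sd)))
  mult <- ifelse(blocks$gc > gc_base, sine_gc_coupling, 1)
  w <- blocks$end - blocks$start
  mult <- mult / sum(mult * w) * sum(w) # genome-mean multiplier 1
  blocks$sine_rate <- sine_density * mult # per Mbp

  place_elems <- function(rate_per_block, len, class, families, fam_prob) {
    counts <- rpois(nrow(blocks), rate_per_block * w / 1e6)
    idx <- rep(seq_len(nrow(blocks)), counts)
    if (length(idx) == 0) return(empty_repeats())
    lo <- blocks$start[idx]
    hi <- pmax(lo, blocks$end[idx] - len)
    starts <- floor(runif(length(idx), lo, hi + 1))
    tibble(chrom = blocks$chrom[idx], start = starts,
           end = pmin(starts + len, chrom_length_bp),
           repeat_class = class,
           family = sample(families, length(idx), replace = TRUE, prob = fam_prob))
  }
  repeats <- bind_rows(
    place_elems(blocks$sine_rate, sine_len, "SINE", c("AluS", "AluY"), c(0.7, 0.3)),
    place_elems(rep(line_density, nrow(blocks)), line_len, "LINE", "L1", 1),
    place_elems(rep(ltr_density, nrow(blocks)), ltr_len, "LTR", "ERV", 1)
  ) |> arrange(.data$chrom, .data$start)

  exclusion <- purrr::map(chroms, function(ch) {
    if (exclusion_fraction == 0) {
      return(tibble(chrom = character(), start = numeric(), end = numeric()))
    }
    k <- 5
    len <- exclusion_fraction * chrom_length_bp / k
    starts <- floor(runif(k, 0, chrom_length_bp - len))
    tibble(chrom = ch, start = starts, end = starts + ceiling(len))
  }) |> list_rbind()
  if (nrow(exclusion) > 0) exclusion <- merge_intervals(exclusion)

  landscape <- genome_landscape(sizes, blocks[, c("chrom", "start", "end", "gc")],
                                repeats = repeats, exclusion = exclusion)
  truth <- list(seed = seed, gc_base = gc_base, gc_block_sd = gc_block_sd,
                sine_density = sine_density, line_density = line_density,
                ltr_density = ltr_density, sine_gc_coupling = sine_gc_coupling,
                exclusion_fraction = exclusion_fraction,
                blocks = blocks)
  list(landscape = landscape, truth = truth)
}

#' Simulate a duplication history on a landscape
#'
#' Donor blocks are placed wholly inside single GC blocks, with the block
#' chosen under weights `lambda_b^theta` where `theta` is solved
#' (monotone root-finding) so that the expected SINE intensity over placed
#' donors equals `donor_enrichment_E` times the mean intensity of the
#' permutation-allowed space -- i.e. the planted enrichment coefficient
#' has expectation exactly `E`. Each insertion receives an acceptor
#' region (`2 * acceptor_flank_bp` centred on a uniform allowed insertion
#' point), two junctions with an AluS planted to overlap the +/-50 bp
#' breakpoint window with probability `junction_alu_prob`, and a
#' pre-integration deletion drawn from a lognormal (in kbp) or none with
#' probability `p_no_deletion`.
#'
#' @param landscape_sim The list returned by [simulate_landscape()].
#' @param n_blocks Number of duplication events (one donor, one acceptor,
#'   two junctions and one pre-integration record each).
#' @param donor_size_range_kbp Donor duplicon size range (study-scale
#'   default 15-180 kbp).
#' @param block_size_range_kbp Inserted duplication-block size range
#'   (study-scale default 150-380 kbp); sets junction spacing and
#'   `insertion_kbp`.
#' @param donor_enrichment_E Planted SINE enrichment multiplier (1 = null).
#' @param junction_alu_prob Probability q that a junction carries a
#'   breakpoint Alu.
#' @param deletion_meanlog,deletion_sdlog Lognormal parameters of the
#'   deletion size (kbp).
#' @param p_no_deletion Probability of a precise, deletion-free insertion.
#' @param acceptor_flank_bp Acceptor half-width.
#' @param seed Integer seed.
#' @return List: `landscape` (with planted junction Alus appended),
#'   `donors`, `acceptors` (region tibbles), `junctions` (tibble with
#'   `chrom`, `breakpoint`, `alu_planted`), `pre_integration` (tibble with
#'   `deletion_kbp` etc.) and `truth`.
#' @export
simulate_duplication_history <- function(landscape_sim,
                                         n_blocks = 20,
                                         donor_size_range_kbp = c(15, 180),
                                         block_size_range_kbp = c(150, 380),
                                         donor_enrichment_E = 1,
                                         junction_alu_prob = 9 / 14,
                                         deletion_meanlog = log(5.8),
                                         deletion_sdlog = 1.1,
                                         p_no_deletion = 1 / 13,
                                         acceptor_flank_bp = 10000,
                                         seed = 1) {
  stopifnot(junction_alu_prob >= 0, junction_alu_prob <= 1,
            all(block_size_range_kbp > 0), all(donor_size_range_kbp > 0),
            donor_enrichment_E > 0)
  landscape <- landscape_sim$landscape
  blocks <- landscape_sim$truth$blocks
  set.seed(as.integer(seed))
  sizes_bp <- floor(runif(n_blocks, donor_size_range_kbp[1] * 1000,
                          donor_size_range_kbp[2] * 1000))
  ins_bp <- floor(runif(n_blocks, block_size_range_kbp[1] * 1000,
                        block_size_range_kbp[2] * 1000))
  max_size <- max(sizes_bp)
  eligible <- blocks[(blocks$end - blocks$start) >= max_size, , drop = FALSE]
  if (nrow(eligible) == 0) abort("landscape GC blocks too small for requested donor sizes")

  # mean SINE intensity of the allowed space (the null expectation)
  allowed <- allowed_space(landscape)
  lam_allowed <- {
    hits <- overlap_hits(allowed, blocks)
    ovw <- pmin(allowed$end[hits$region], blocks$end[hits$element]) -
      pmax(allowed$start[hits$region], blocks$start[hits$element])
    sum(ovw * blocks$sine_rate[hits$element]) / sum(ovw)
  }
  lam <- eligible$sine_rate
  target <- donor_enrichment_E * lam_allowed
  if (target < min(lam) || target > max(lam)) {
    abort("planted enrichment E is outside the range attainable from the block intensities")
  }
  f <- function(theta) sum(lam^theta * lam) / sum(lam^theta) - target
  theta <- if (abs(f(0)) < 1e-9) 0 else uniroot(f, c(-60, 60), tol = 1e-10)$root
  wgt <- lam^theta
  pick <- sample.int(nrow(eligible), n_blocks, replace = TRUE, prob = wgt)
  don_start <- floor(runif(n_blocks, eligible$start[pick],
                           eligible$end[pick] - sizes_bp + 1))
  donors <- region_tbl(eligible$chrom[pick], don_start, don_start + sizes_bp,
                       name = sprintf("donor-%02d", seq_len(n_blocks)), role = "donor")

  # insertion points and acceptor regions in allowed space
  pts <- permute_regions(
    region_tbl(rep("x", n_blocks), 0, 1),
    allowed[allowed$end - allowed$start > 2 * acceptor_flank_bp, , drop = FALSE]
  )
  chrom_size <- landscape$chrom_sizes$size[match(pts$chrom, landscape$chrom_sizes$chrom)]
  acc_start <- pmax(0, pts$start - acceptor_flank_bp)
  acc_end <- pmin(chrom_size, pts$start + acceptor_flank_bp)
  acceptors <- region_tbl(pts$chrom, acc_start, acc_end,
                          name = sprintf("acceptor-%02d", seq_len(n_blocks)),
                          role = "acceptor")

  junctions <- tibble(
    chrom = rep(pts$chrom, each = 2),
    breakpoint = as.numeric(rbind(pts$start, pmin(chrom_size, pts$start + ins_bp))),
    alu_planted = rbinom(2 * n_blocks, 1, junction_alu_prob) == 1
  )
  sine_len <- 300
  planted <- junctions[junctions$alu_planted, , drop = FALSE]
  if (nrow(planted) > 0) {
    off <- floor(runif(nrow(planted), -50 - (sine_len - 1), 51))
    new_reps <- tibble(chrom = planted$chrom,
                       start = pmax(0, planted$breakpoint + off),
                       end = planted$breakpoint + off + sine_len,
                       repeat_class = "SINE", family = "AluS")
    landscape$repeats <- bind_rows(landscape$repeats, new_reps) |>
      arrange(.data$chrom, .data$start)
  }

  has_del <- rbinom(n_blocks, 1, 1 - p_no_deletion) == 1
  del_kbp <- ifelse(has_del, round(rlnorm(n_blocks, deletion_meanlog, deletion_sdlog), 1), 0)
  pre_integration <- tibble(
    species = "synthetic", chrom = pts$chrom,
    anchor_start = pts$start,
    anchor_end = pts$start + del_kbp * 1000,
    deletion_kbp = del_kbp,
    insertion_kbp = ins_bp / 1000
  )

  truth <- list(seed = seed, donor_enrichment_E = donor_enrichment_E,
                junction_alu_prob = junction_alu_prob,
                deletion_meanlog = deletion_meanlog,
                deletion_sdlog = deletion_sdlog,
                p_no_deletion = p_no_deletion,
                theta = theta, lambda_allowed_mean = lam_allowed,
                donor_sizes_bp = sizes_bp, insertion_sizes_bp = ins_bp)
  list(landscape = landscape, donors = donors, acceptors = acceptors,
       junctions = junctions, pre_integration = pre_integration, truth = truth)
}

## ---- codon family simulator -------------------------------------------

# per-codon substitution menu: for codon index, the reachable sense codons
# with their relative rates (kappa for transitions, omega for nonsynonymous)
codon_moves <- function() {
  if (is.null(.dupliconevo_cache$moves)) {
    tab <- codon_table()
    sc <- sense_codons()
    moves <- lapply(sc, function(cd) {
      b <- strsplit(cd, "")[[1]]
      out <- list()
      for (pos in 1:3) {
        for (alt in setdiff(CODON_BASES, b[pos])) {
          nb <- b; nb[pos] <- alt
          nn <- paste0(nb, collapse = "")
          if (tab[[nn]] == "*") next
          out[[length(out) + 1]] <- list(
            to = nn,
            is_ts = is_transition(b[pos], alt),
            is_nonsyn = tab[[cd]] != tab[[nn]]
          )
        }
      }
      list(to = vapply(out, `[[`, character(1), "to"),
           is_ts = vapply(out, `[[`, logical(1), "is_ts"),
           is_nonsyn = vapply(out, `[[`, logical(1), "is_nonsyn"))
    })
    names(moves) <- sc
    .dupliconevo_cache$moves <- moves
  }
  .dupliconevo_cache$moves
}

codon_rates <- function(codons, kappa, omega, moves) {
  vapply(codons, function(cd) {
    m <- moves[[cd]]
    sum(ifelse(m$is_ts, kappa, 1) * ifelse(m$is_nonsyn, omega, 1))
  }, numeric(1))
}

# Gillespie evolution of a codon vector along one branch. Branch length is
# expected substitutions per codon at neutrality (omega = 1), under the
# given kappa; rates are normalized by the neutral mean total rate.
evolve_branch <- function(codons, t, kappa, omega, moves, mean_rate0) {
  rates <- codon_rates(codons, kappa, omega, moves) / mean_rate0
  time <- 0
  repeat {
    R <- sum(rates)
    if (R <= 0) break
    time <- time + rexp(1, R)
    if (time > t) break
    i <- sample.int(length(codons), 1, prob = rates)
    m <- moves[[codons[i]]]
    w <- ifelse(m$is_ts, kappa, 1) * ifelse(m$is_nonsyn, omega, 1)
    j <- sample.int(length(w), 1, prob = w)
    codons[i] <- m$to[j]
    rates[i] <- codon_rates(codons[i], kappa, omega, moves) / mean_rate0
  }
  codons
}

#' Simulate a codon paralog family under per-group selection
#'
#' A root sequence of uniform sense codons evolves, per group, first along
#' an ancestral branch and then along one branch per member, by exact
#' (Gillespie) simulation of single-base codon changes with rate
#' multiplier `kappa` for transitions and `omega` for nonsynonymous
#' changes; moves into stop codons have rate zero, so no stop is ever
#' emitted. Branch lengths are expected substitutions per codon at
#' neutrality.
#'
#' @param group_sizes Named integer vector, members per group.
#' @param omega_per_group Named numeric vector of per-group omega; a
#'   single unnamed value is recycled.
#' @param kappa Transition/transversion rate ratio.
#' @param n_codons Codons per sequence.
#' @param branch_length Tip branch length; `anc_branch_length` is the
#'   shared within-group ancestral branch.
#' @param anc_branch_length Ancestral branch length per group.
#' @param seed Integer seed.
#' @return List: `sequences` (named character vector, names
#'   `<group>_<i>`), `groups` (named character vector), `truth`.
#' @export
simulate_codon_family <- function(group_sizes = c(A = 4, B = 4),
                                  omega_per_group = 1,
                                  kappa = 2,
                                  n_codons = 300,
                                  branch_length = 0.15,
                                  anc_branch_length = branch_length,
                                  seed = 1) {
  stopifnot(all(group_sizes >= 1), kappa > 0, all(omega_per_group > 0))
  if (is.null(names(omega_per_group)) && length(omega_per_group) == 1) {
    omega_per_group <- setNames(rep(omega_per_group, length(group_sizes)),
                                names(group_sizes))
  }
  stopifnot(all(names(group_sizes) %in% names(omega_per_group)))
  set.seed(as.integer(seed))
  moves <- codon_moves()
  sc <- sense_codons()
  mean_rate0 <- mean(codon_rates(sc, kappa, 1, moves))
  root <- sample(sc, n_codons, replace = TRUE)
  seqs <- character(0)
  grp <- character(0)
  for (g in names(group_sizes)) {
    om <- omega_per_group[[g]]
    anc <- evolve_branch(root, anc_branch_length, kappa, om, moves, mean_rate0)
    for (i in seq_len(group_sizes[[g]])) {
      tip <- evolve_branch(anc, branch_length, kappa, om, moves, mean_rate0)
      nm <- sprintf("%s_%d", g, i)
      seqs[nm] <- paste0(tip, collapse = "")
      grp[nm] <- g
    }
  }
  truth <- list(seed = seed, kappa = kappa, omega_per_group = omega_per_group,
                n_codons = n_codons, branch_length = branch_length,
                anc_branch_length = anc_branch_length)
  list(sequences = seqs, groups = grp, truth = truth)
}
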