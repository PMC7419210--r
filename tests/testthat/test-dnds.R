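test_that("the genetic code table matches an independent reference", {
  skip_if_not_installed("Biostrings")
  codes <- Biostrings::GENETIC_CODE
  for (cd in names(codes)) {
    if (codes[[cd]] == "*") next
    expect_equal(oracle_codon_aa(cd), codes[[cd]], label = cd)
  }
  expect_equal(length(sense_codons()), 61)
})

test_that("potential_sites handles canonical codons", {
  expect_equal(potential_sites("TTT"), c(n_nonsyn = 8 / 3, n_syn = 1 / 3))
  expect_equal(potential_sites("ATG"), c(n_nonsyn = 3, n_syn = 0))
  # fourfold-degenerate third position contributes one full synonymous site
  for (R in c(0.5, 1, 4)) {
    expect_gte(potential_sites("GGG", R)[["n_syn"]], 1)
  }
  expect_error(potential_sites("TAA"), "stop")
  expect_error(potential_sites("NNN"), "invalid")
})

test_that("potential_sites matches the enumeration oracle on all sense codons", {
  for (R in c(0.5, 2)) {
    for (cd in sense_codons()) {
      expect_equal(potential_sites(cd, R), oracle_potential_sites(cd, R),
                   tolerance = 1e-12, label = paste(cd, "R =", R))
    }
  }
  # site conservation: n + s = 3 for every codon
  for (cd in sense_codons()) {
    expect_equal(sum(potential_sites(cd)), 3)
    expect_equal(sum(potential_sites(cd, 7)), 3)
  }
})

test_that("pairwise_differences averages over stop-free pathways", {
  expect_equal(pairwise_differences("AAA", "AAA"), c(Nd = 0, Sd = 0))
  # two pathways: via GTT (1 nonsyn + 1 syn) and via TTA (2 nonsyn)
  expect_equal(pairwise_differences("TTT", "GTA"), c(Nd = 1.5, Sd = 0.5))
  expect_error(pairwise_differences("TGA", "TGG"), "stop")
})

test_that("pairwise_differences matches the path-enumeration oracle", {
  set.seed(61)
  sc <- sense_codons()
  pairs <- cbind(sample(sc, 500, replace = TRUE), sample(sc, 500, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(pairwise_differences(pairs[i, 1], pairs[i, 2]),
                 oracle_pairwise_differences(pairs[i, 1], pairs[i, 2]),
                 label = paste(pairs[i, ], collapse = "/"))
  }
  # include three-difference codons explicitly
  expect_equal(pairwise_differences("AAA", "GGG"),
               oracle_pairwise_differences("AAA", "GGG"))
  expect_equal(pairwise_differences("TTT", "GCA"),
               oracle_pairwise_differences("TTT", "GCA"))
})

test_that("dn_ds on a small hand alignment matches direct counting", {
  # 5 codons; differences: AAA->AAG (syn), TTT->CTT (nonsyn), GGC->GGT (syn)
  s1 <- "AAATTTGGCATGCCC"
  s2 <- "AAGCTTGGTATGCCC"
  d <- dn_ds(s1, s2, correction = "proportion")
  expect_equal(d$Nd, 1)
  expect_equal(d$Sd, 2)
  st <- vapply(c("AAA", "TTT", "GGC", "ATG", "CCC",
                 "AAG", "CTT", "GGT", "ATG", "CCC"),
               function(cd) oracle_potential_sites(cd), numeric(2))
  expect_equal(d$N_sites, sum(st["n_nonsyn", ]) / 2)
  expect_equal(d$S_sites, sum(st["n_syn", ]) / 2)
  expect_equal(d$dN, d$Nd / d$N_sites)
  expect_equal(d$dS, d$Sd / d$S_sites)
  expect_equal(d$var_dN, d$pN * (1 - d$pN) / d$N_sites)
  expect_equal(d$Z, d$D / sqrt(d$var_dN + d$var_dS))
  expect_equal(d$p, pnorm(d$Z, lower.tail = FALSE))
})

test_that("dn_ds handles identical, gapped and saturated input", {
  s <- "ATGAAACCC"
  d <- dn_ds(s, s)
  expect_equal(c(d$dN, d$dS, d$Z), c(0, 0, 0))
  expect_equal(d$p, 0.5)

  # codons containing gaps or ambiguity are pairwise-deleted
  g <- dn_ds("ATG---CCC", "ATGAAACCC")
  expect_equal(g$n_codons, 2)
  expect_equal(g$n_skipped, 1)

  # Jukes-Cantor undefined at pS >= 3/4
  many <- paste(rep("AAA", 20), collapse = "")
  mostly_syn <- paste(rep("AAG", 20), collapse = "")
  sat <- dn_ds(many, mostly_syn)
  expect_true(sat$saturated)
  expect_true(is.na(sat$dS))
  # the uncorrected proportion stays defined even past the JC limit
  prop <- dn_ds(many, mostly_syn, correction = "proportion")
  expect_equal(prop$dS, prop$pS)
})

test_that("dn_ds is symmetric in its arguments", {
  set.seed(71)
  for (i in 1:10) {
    a <- random_sense_seq(40)
    b <- random_sense_seq(40)
    d1 <- dn_ds(a, b)
    d2 <- dn_ds(b, a)
    for (col in c("N_sites", "S_sites", "Nd", "Sd", "dN", "dS", "D", "Z", "p")) {
      expect_equal(d1[[col]], d2[[col]], label = col)
    }
  }
})

test_that("neutral simulation gives mean Z near zero", {
  zs <- vapply(1:30, function(r) {
    fam <- simulate_codon_family(c(G = 2), omega_per_group = 1, kappa = 1,
                                 n_codons = 200, branch_length = 0.1,
                                 anc_branch_length = 0, seed = 300 + r)
    dn_ds(fam$sequences[1], fam$sequences[2])$Z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 2.5 / sqrt(30))
})

test_that("NG dN/dS recovers omega from the codon simulator within 15%", {
  # kappa = 2 simulated; the modified method with R = kappa/2 = 1 matches
  # the mutation opportunity exactly
  for (om in c(0.2, 1, 3)) {
    dn <- numeric(50)
    ds <- numeric(50)
    for (r in 1:50) {
      fam <- simulate_codon_family(c(A = 2), omega_per_group = om, kappa = 2,
                                   n_codons = 300, branch_length = 0.2,
                                   anc_branch_length = 0, seed = 1000 * om + r)
      d <- dn_ds(fam$sequences[1], fam$sequences[2], ts_tv_ratio = 1)
      dn[r] <- d$dN
      ds[r] <- d$dS
    }
    est <- mean(dn) / mean(ds)
    expect_equal(est, om, tolerance = 0.15, label = sprintf("omega = %s", om))
  }
})

test_that("group_selection_scan scans groups by exon and drops excluded exons", {
  fam <- simulate_codon_family(c(HSA = 3, CJA = 3),
                               omega_per_group = c(HSA = 3, CJA = 0.5),
                               n_codons = 120, seed = 5)
  part <- tibble::tibble(exon = c("exon1", "exon8"),
                         start_codon = c(1, 61), end_codon = c(60, 120))
  scan <- group_selection_scan(fam$sequences, fam$groups, part)
  expect_false("exon8" %in% scan$exon)
  expect_equal(sort(unique(scan$group)), c("CJA", "HSA"))
  expect_equal(unique(scan$n_pairs), 3)

  # groups with < 2 members are skipped with a warning
  expect_warning(
    group_selection_scan(fam$sequences[1:3],
                         setNames(c("A", "A", "solo"),
                                  names(fam$sequences)[1:3])),
    "fewer than 2")
})

test_that("selection scan attains high power under positive selection", {
  sig <- vapply(1:100, function(r) {
    fam <- simulate_codon_family(c(G = 4), omega_per_group = 3, kappa = 2,
                                 n_codons = 300, branch_length = 0.1,
                                 seed = 7000 + r)
    group_selection_scan(fam$sequences, fam$groups, ts_tv_ratio = 1)$significant
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("selection scan false-positive rate is near nominal under neutrality", {
  sig <- vapply(1:200, function(r) {
    fam <- simulate_codon_family(c(G = 4), omega_per_group = 1, kappa = 1,
                                 n_codons = 300, branch_length = 0.1,
                                 seed = 8000 + r)
    group_selection_scan(fam$sequences, fam$groups)$significant
  }, logical(1))
  expect_lt(abs(mean(sig) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("dnds tidiers expose the configuration", {
  d <- dn_ds("ATGAAA", "ATGAAG")
  expect_s3_class(tidy(d), "tbl_df")
  expect_equal(glance(d)$correction, "jukes_cantor")
  fam <- simulate_codon_family(c(A = 2, B = 2), omega_per_group = 1,
                               n_codons = 50, seed = 9)
  scan <- group_selection_scan(fam$sequences, fam$groups)
  expect_s3_class(autoplot(scan), "ggplot")
  expect_equal(glance(scan)$alpha, 0.05)
})
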