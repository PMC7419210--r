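# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive everything from first principles rather
# than calling package internals.

oracle_codon_aa <- function(codon) {
  # independent genetic-code lookup built from a base-by-base table
  aa3 <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  unname(aa3[codon])
}

oracle_neighbors <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      nb <- b
      nb[pos] <- alt
      out <- c(out, paste0(nb, collapse = ""))
    }
  }
  out
}

oracle_is_ts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  a <- substr(c1, pos, pos)
  b <- substr(c2, pos, pos)
  paste0(sort(c(a, b)), collapse = "") %in% c("AG", "CT")
}

# weighted potential sites by enumeration over the nine neighbors
oracle_potential_sites <- function(codon, R = 0.5) {
  aa0 <- oracle_codon_aa(codon)
  s <- 0
  b <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    neigh <- character(0)
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      nb <- b
      nb[pos] <- alt
      neigh <- c(neigh, paste0(nb, collapse = ""))
    }
    w <- vapply(neigh, function(nn) {
      if (oracle_is_ts(codon, nn)) R / (R + 1) else (1 / (R + 1)) / 2
    }, numeric(1))
    aa <- vapply(neigh, oracle_codon_aa, character(1))
    keep <- aa != "*"
    if (!any(keep)) next
    w <- w[keep] / sum(w[keep])
    s <- s + sum(w[aa[keep] == aa0])
  }
  c(n_nonsyn = 3 - s, n_syn = s)
}

# pathway-averaged differences by full path enumeration
oracle_pairwise_differences <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  if (length(pos) == 0) return(c(Nd = 0, Sd = 0))
  ords <- if (length(pos) == 1) list(pos) else {
    pm <- as.matrix(expand.grid(rep(list(pos), length(pos))))
    pm <- pm[apply(pm, 1, function(r) length(unique(r)) == length(pos)), , drop = FALSE]
    lapply(seq_len(nrow(pm)), function(i) pm[i, ])
  }
  tot_n <- 0; tot_s <- 0; nv <- 0
  for (ord in ords) {
    cur <- b1; nd <- 0; sd_ <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b2[p]
      if (oracle_codon_aa(paste0(nxt, collapse = "")) == "*") { ok <- FALSE; break }
      if (oracle_codon_aa(paste0(cur, collapse = "")) ==
            oracle_codon_aa(paste0(nxt, collapse = ""))) sd_ <- sd_ + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot_n <- tot_n + nd; tot_s <- tot_s + sd_; nv <- nv + 1 }
  }
  if (nv == 0) return(c(Nd = NA_real_, Sd = NA_real_))
  c(Nd = tot_n / nv, Sd = tot_s / nv)
}

# brute-force count of distinct elements overlapping a region set
oracle_overlap_elements <- function(regions, elems) {
  hit <- logical(nrow(elems))
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(elems))) {
      if (regions$chrom[i] == elems$chrom[j] &&
            regions$start[i] < elems$end[j] && elems$start[j] < regions$end[i]) {
        hit[j] <- TRUE
      }
    }
  }
  sum(hit)
}

# exhaustive two-sample KS statistic over all sample points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000) {
  starts <- sample.int(max_pos - 10, n, replace = TRUE)
  region_tbl(sample(chroms, n, replace = TRUE), starts,
             starts + sample.int(50, n, replace = TRUE))
}

random_sense_seq <- function(n_codons) {
  paste0(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

tiny_landscape <- function(seed = 1, ...) {
  simulate_landscape(n_chroms = 2, chrom_length_bp = 2e6, gc_block_bp = 1e5,
                     seed = seed, ...)
}
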