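#' Observed feature values for a region set
#'
#' For `"gc"` the per-region value is the overlap-weighted GC fraction and
#' the aggregate is their mean; for `"sine"`/`"line"` the per-region value
#' is the distinct-element count of the region and the aggregate is the
#' total of the per-region counts. Region sets are expected to be
#' nonredundant ([merge_intervals()]), in which case this total equals the
#' set-level distinct count of [overlap_elements()].
#'
#' @param regions Region tibble.
#' @param landscape A [genome_landscape()].
#' @param feature One of `"gc"`, `"sine"`, `"line"`.
#' @return List with `per_region` (numeric vector) and `aggregate` (scalar).
#' @export
observed_feature <- function(regions, landscape, feature = c("gc", "sine", "line")) {
  feature <- match.arg(feature)
  stopifnot(inherits(landscape, "genome_landscape"))
  validate_regions(regions)
  sz <- landscape$chrom_sizes$size[match(regions$chrom, landscape$chrom_sizes$chrom)]
  if (anyNA(sz) || any(regions$end > sz)) {
    abort("region outside landscape chromosome bounds")
  }
  if (feature == "gc") {
    per <- region_gc(regions, landscape$gc)
    list(per_region = per, aggregate = mean(per, na.rm = TRUE))
  } else {
    cls <- toupper(feature)
    per <- overlap_counts_per_region(regions, landscape$repeats, cls)
    list(per_region = per, aggregate = sum(per))
  }
}

# closure computing per-region/aggregate feature values with the
# per-chromosome subject ranges built once (hot path of the permutation null)
feature_evaluator <- function(landscape, feature) {
  if (feature == "gc") {
    subj <- landscape$gc
    vals <- subj$gc
  } else {
    subj <- landscape$repeats[landscape$repeats$repeat_class == toupper(feature), ,
                              drop = FALSE]
    vals <- NULL
  }
  by_chrom <- split(seq_len(nrow(subj)), subj$chrom)
  ir <- lapply(by_chrom, function(i) {
    IRanges::IRanges(start = subj$start[i] + 1, end = subj$end[i])
  })
  function(regions) {
    per <- if (is.null(vals)) integer(nrow(regions)) else rep(NA_real_, nrow(regions))
    for (ch in unique(regions$chrom)) {
      si <- ir[[ch]]
      ri <- which(regions$chrom == ch)
      if (is.null(si)) next
      q <- IRanges::IRanges(start = regions$start[ri] + 1, end = regions$end[ri])
      if (is.null(vals)) {
        per[ri] <- IRanges::countOverlaps(q, si)
      } else {
        ov <- IRanges::findOverlaps(q, si)
        qi <- S4Vectors::queryHits(ov)
        sj <- by_chrom[[ch]][S4Vectors::subjectHits(ov)]
        w <- pmin(regions$end[ri][qi], subj$end[sj]) -
          pmax(regions$start[ri][qi], subj$start[sj])
        num <- tapply(w * vals[sj], qi, sum)
        den <- tapply(w, qi, sum)
        per[ri[as.integer(names(num))]] <- as.numeric(num) / as.numeric(den)
      }
    }
    if (is.null(vals)) list(per_region = per, aggregate = sum(per))
    else list(per_region = per, aggregate = mean(per, na.rm = TRUE))
  }
}

#' Random length-preserving placement of regions
#'
#' Places one interval per input interval, of identical length, with its
#' start drawn uniformly over every genome position at which the interval
#' fits entirely inside a single allowed segment. Placements are
#' independent; mutual overlap among placed intervals is permitted, and
#' chromosome identity is not preserved (each placement may land on any
#' chromosome with an allowed segment large enough).
#'
#' @param regions Region tibble (only the lengths are used).
#' @param allowed Region tibble of allowed segments (see [allowed_space()]).
#' @return Region tibble of placed intervals, one row per input row.
#' @export
permute_regions <- function(regions, allowed) {
  validate_regions(regions)
  validate_regions(allowed, "allowed space")
  lens <- regions$end - regions$start
  seg_len <- allowed$end - allowed$start
  out_chrom <- character(length(lens))
  out_start <- numeric(length(lens))
  for (i in seq_along(lens)) {
    L <- lens[i]
    fits <- seg_len >= L
    if (!any(fits)) {
      nm <- if ("name" %in% names(regions) && !is.na(regions$name[i]))
        regions$name[i] else sprintf("row %d", i)
      abort(sprintf("region %s (length %d) is longer than every allowed segment", nm, L))
    }
    npos <- seg_len[fits] - L + 1
    total <- sum(npos)
    u <- floor(runif(1, min = 0, max = total))
    u <- min(u, total - 1) # guard the measure-zero upper edge
    cum <- cumsum(npos)
    k <- findInterval(u, c(0, cum), rightmost.closed = FALSE) # segment index in fits
    seg <- which(fits)[k]
    offset <- u - c(0, cum)[k]
    out_chrom[i] <- allowed$chrom[seg]
    out_start[i] <- allowed$start[seg] + offset
  }
  region_tbl(out_chrom, out_start, out_start + lens,
             name = if ("name" %in% names(regions)) regions$name else NA_character_,
             role = if ("role" %in% names(regions)) regions$role else "other")
}

#' Null distribution of a feature under random placement
#'
#' Draws `n_permutations` independent placements of the region set inside
#' the allowed space and records the aggregate feature value of each
#' placement set. For GC the per-region values of every placement are also
#' pooled (capped at `pool_cap` by seeded subsampling) to serve as the
#' Kolmogorov-Smirnov null sample. Deterministic under a fixed seed.
#'
#' @inheritParams observed_feature
#' @param n_permutations Number of placements (the full-scale analysis
#'   uses 10,000).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @param pool_cap Maximum pooled per-region values retained.
#' @return List of class `null_distribution`: `feature`,
#'   `per_permutation_values`, `per_region_values` (GC only, else `NULL`),
#'   `mean`, `sd`, `n_permutations`.
#' @export
null_distribution <- function(regions, landscape, feature = c("gc", "sine", "line"),
                              n_permutations = 1000, seed = NULL, pool_cap = 1e5) {
  feature <- match.arg(feature)
  stopifnot(n_permutations >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  allowed <- allowed_space(landscape)
  evaluate <- feature_evaluator(landscape, feature)
  per_perm <- numeric(n_permutations)
  pool <- if (feature == "gc") vector("list", n_permutations) else NULL
  for (b in seq_len(n_permutations)) {
    placed <- permute_regions(regions, allowed)
    obs <- evaluate(placed)
    per_perm[b] <- obs$aggregate
    if (feature == "gc") pool[[b]] <- obs$per_region
  }
  per_region <- NULL
  if (feature == "gc") {
    per_region <- unlist(pool)
    per_region <- per_region[!is.na(per_region)]
    if (length(per_region) > pool_cap) {
      per_region <- per_region[sample.int(length(per_region), pool_cap)]
    }
  }
  structure(list(feature = feature,
                 per_permutation_values = per_perm,
                 per_region_values = per_region,
                 mean = mean(per_perm), sd = sd(per_perm),
                 n_permutations = n_permutations),
            class = "null_distribution")
}

#' One-tailed empirical p-value via the Z-score transformation
#'
#' `z = (observed - mean(null)) / sd(null)`; the p-value is the upper-tail
#' standard normal probability (enrichment direction). Set
#' `direction = "depletion"` for the lower tail.
#'
#' @param observed Observed aggregate value.
#' @param null A [null_distribution()] (or any list with `mean` and `sd`).
#' @param direction `"enrichment"` (default) or `"depletion"`.
#' @return Named list with `z` and `p`.
#' @export
empirical_p_z <- function(observed, null, direction = c("enrichment", "depletion")) {
  direction <- match.arg(direction)
  if (!is.finite(null$sd) || null$sd <= 0) {
    abort("degenerate null distribution: sd is zero")
  }
  z <- (observed - null$mean) / null$sd
  p <- pnorm(z, lower.tail = (direction == "depletion"))
  list(z = z, p = p)
}

#' Two-sample Kolmogorov-Smirnov test for GC content
#'
#' D is the supremum gap between the two empirical CDFs; the p-value comes
#' from the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n1 * n2 / (n1 + n2)) * D`.
#'
#' @param observed_per_region Observed per-region GC values.
#' @param null_per_region Pooled null per-region GC values.
#' @return Named list with `D` and `p`.
#' @export
ks_gc_test <- function(observed_per_region, null_per_region) {
  x <- observed_per_region[!is.na(observed_per_region)]
  y <- null_per_region[!is.na(null_per_region)]
  if (length(x) == 0 || length(y) == 0) abort("empty sample in KS test")
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= length(x), 1 / length(x), -1 / length(y)))
  # at ties only the last cumulative value is a CDF evaluation point
  ws <- sort(w)
  keep <- c(diff(ws) != 0, TRUE)
  D <- max(abs(z[keep]))
  ne <- length(x) * length(y) / (length(x) + length(y))
  list(D = D, p = kolmogorov_sf(sqrt(ne) * D))
}

# Kolmogorov asymptotic survival function: 2 * sum (-1)^(k-1) exp(-2 k^2 x^2)
kolmogorov_sf <- function(x, kmax = 100) {
  if (x <= 0) return(1)
  k <- seq_len(kmax)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(1, max(0, p))
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value in `[0, 1]`.
#' @param n_tests Number of tests in the family (9 for the canonical
#'   3 region classes x 3 features design).
#' @return `min(1, p_raw * n_tests)`.
#' @export
bonferroni <- function(p_raw, n_tests = 9) {
  if (any(p_raw < 0 | p_raw > 1)) abort("p_raw outside [0, 1]")
  stopifnot(n_tests >= 1)
  pmin(1, p_raw * n_tests)
}

#' Binomial standard error of a p-value
#'
#' `SE = sqrt(p * (1 - p) / n)` where `n` is the number of regions tested.
#' This is the +/- term attached to each permutation p-value in the
#' enrichment table.
#'
#' @param p p-value in `[0, 1]`.
#' @param n_regions Number of regions tested (must be >= 1).
#' @return Standard error.
#' @examples
#' p_value_se(3.7e-8, 63) # ~2.4e-5
#' @export
p_value_se <- function(p, n_regions) {
  if (any(p < 0 | p > 1)) abort("p outside [0, 1]")
  if (any(n_regions < 1)) abort("n_regions must be >= 1")
  sqrt(p * (1 - p) / n_regions)
}

#' Run the full permutation-enrichment analysis
#'
#' One test per (region set x feature): the observed aggregate, a
#' length-preserving permutation null, the enrichment coefficient
#' `E = observed / mean(null)`, a raw p-value (Kolmogorov-Smirnov for GC,
#' upper-tail Z-score for repeat counts; the Z-based p is reported for GC
#' too), Bonferroni correction over all tests run, the binomial SE of the
#' raw p, and the significance flag `p_corrected + SE <= 0.05`.
#'
#' @param landscape A [genome_landscape()].
#' @param region_sets Named list of region tibbles (names become `role`).
#' @param features Character subset of `c("gc", "sine", "line")`.
#' @param n_permutations Permutations per test.
#' @param seed Integer seed; each test gets a derived substream seed so
#'   results are independent of test order.
#' @param n_tests Bonferroni family size; defaults to
#'   `length(region_sets) * length(features)`.
#' @return Tibble of class `enrichment_result`, one row per test, columns
#'   `role`, `feature`, `n_regions`, `observed`, `null_mean`, `null_sd`,
#'   `E`, `z`, `p_z`, `p_ks` (GC only), `p_raw`, `p_corrected`, `se`,
#'   `significant`.
#' @export
run_enrichment <- function(landscape, region_sets,
                           features = c("gc", "sine", "line"),
                           n_permutations = 1000, seed = 1,
                           n_tests = length(region_sets) * length(features)) {
  stopifnot(length(region_sets) >= 1, length(features) >= 1)
  features <- match.arg(features, c("gc", "sine", "line"), several.ok = TRUE)
  if (is.null(names(region_sets))) {
    names(region_sets) <- paste0("set", seq_along(region_sets))
  }
  grid <- expand.grid(role = names(region_sets), feature = features,
                      stringsAsFactors = FALSE)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    role <- grid$role[i]
    feature <- grid$feature[i]
    regions <- region_sets[[role]]
    sub_seed <- as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647)
    obs <- observed_feature(regions, landscape, feature)
    null <- null_distribution(regions, landscape, feature,
                              n_permutations = n_permutations, seed = sub_seed)
    zp <- empirical_p_z(obs$aggregate, null)
    p_ks <- NA_real_
    if (feature == "gc") {
      p_ks <- ks_gc_test(obs$per_region, null$per_region_values)$p
    }
    p_raw <- if (feature == "gc") p_ks else zp$p
    tibble(role = role, feature = feature, n_regions = nrow(regions),
           observed = obs$aggregate, null_mean = null$mean, null_sd = null$sd,
           E = obs$aggregate / null$mean, z = zp$z, p_z = zp$p, p_ks = p_ks,
           p_raw = p_raw)
  })
  out <- list_rbind(rows) |>
    mutate(p_corrected = bonferroni(.data$p_raw, n_tests),
           se = p_value_se(.data$p_raw, .data$n_regions),
           significant = (.data$p_corrected + .data$se) <= 0.05)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "n_tests") <- n_tests
  attr(out, "seed") <- seed
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Serialize an enrichment table in the classic layout
#'
#' One row per region class, one `"E, p +/- SE"` cell per feature, with an
#' asterisk where `p_corrected + SE <= 0.05`.
#'
#' @param x An `enrichment_result`.
#' @param path Optional path; when given the table is written as TSV.
#' @return Tibble in wide layout (invisibly when written).
#' @export
format_enrichment_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "enrichment_result"))
  wide <- x |>
    mutate(cell = sprintf("%.2f, %.3g ± %.2g%s", .data$E, .data$p_raw, .data$se,
                          ifelse(.data$significant, " *", ""))) |>
    select("role", "n_regions", "feature", "cell") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "cell")
  if (!is.null(path)) {
    utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(wide))
  }
  wide
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_tests = attr(x, "n_tests"),
         n_permutations = attr(x, "n_permutations"),
         seed = attr(x, "seed"),
         n_significant = sum(x$significant))
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(x)
}

#' Plot enrichment coefficients
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot: E per (role, feature), significant tests filled.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$feature, y = .data$E,
                                       fill = .data$significant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~role) +
    ggplot2::labs(y = "enrichment coefficient E (observed / null mean)",
                  x = NULL, fill = "corrected p + SE ≤ 0.05") +
    ggplot2::theme_minimal()
}
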