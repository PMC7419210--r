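#' Genomic interval tibbles
#'
#' Throughout the package a *region set* is an ordinary tibble with at least
#' the columns `chrom` (character), `start` and `end` (0-based, half-open
#' base offsets, so an interval covers bases `start .. end - 1`). Optional
#' columns `name` and `role` (one of `"donor"`, `"acceptor"`,
#' `"pre_integration"`, `"block"`, `"other"`) are carried along untouched by
#' the interval algebra. Every interval must satisfy `0 <= start < end`.
#'
#' @param chrom Character vector of chromosome identifiers.
#' @param start,end Numeric vectors of 0-based half-open coordinates.
#' @param name Optional labels.
#' @param role Optional shared role label recycled across rows.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `role`.
#' @examples
#' region_tbl("chr1", 0, 100, role = "donor")
#' @export
region_tbl <- function(chrom, start, end, name = NA_character_, role = "other") {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = as.character(name),
    role = as.character(role)
  )
  validate_regions(x)
  x
}

validate_regions <- function(x, what = "region set") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0)) abort(sprintf("%s has negative start coordinates", what))
    if (any(x$end <= x$start)) {
      bad <- which(x$end <= x$start)[1]
      abort(sprintf("%s has zero- or negative-length interval at row %d (start %s, end %s)",
                    what, bad, format(x$start[bad]), format(x$end[bad])))
    }
  }
  invisible(x)
}

#' Read a BED file into a region tibble
#'
#' Reads 3-6 column tab-separated BED. Coordinates are interpreted as
#' 0-based half-open by default; set `one_based = TRUE` for genome-browser
#' style 1-based inclusive coordinates (start is shifted down by one).
#' Input row order and chromosome names are preserved verbatim.
#'
#' @param path Path to a BED file.
#' @param role Role label attached to every interval.
#' @param one_based If `TRUE`, treat input as 1-based inclusive.
#' @return A region tibble (see [region_tbl()]).
#' @export
read_bed <- function(path, role = "other", one_based = FALSE) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(region_tbl(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated columns",
                  which(nf < 3)[1], path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED line %d in %s: non-numeric coordinate",
                  which(is.na(start) | is.na(end))[1], path))
  }
  if (one_based) start <- start - 1
  name <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 4) fields[[i]][4] else NA_character_
  }, character(1))
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("BED line %d in %s: start >= end (zero-length intervals are forbidden)",
                  bad[1], path))
  }
  region_tbl(chrom, start, end, name = name, role = role)
}

#' Write a region tibble as BED
#'
#' @param x Region tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_regions(x)
  nm <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else rep(".", nrow(x))
  writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start), as.integer(x$end), nm),
             path)
  invisible(path)
}

#' Merge overlapping or abutting intervals
#'
#' Coalesces intervals on the same chromosome that overlap or abut
#' (`end == start`), returning the nonredundant union sorted by
#' `(chrom, start)`. This is how redundant donor/acceptor segments are
#' reduced to nonredundant region sets before enrichment testing.
#'
#' @param x Region tibble.
#' @return Merged region tibble; `name` becomes `NA`, `role` is kept when
#'   unique in the input.
#' @examples
#' merge_intervals(region_tbl("chr1", c(10, 40), c(50, 80)))
#' @export
merge_intervals <- function(x) {
  validate_regions(x)
  role <- if ("role" %in% names(x) && length(unique(x$role)) == 1 && nrow(x) > 0)
    x$role[1] else "other"
  if (nrow(x) == 0) return(region_tbl(character(), numeric(), numeric(), role = role))
  x |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(.data$start > cummax_lag_end(.data$end))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    mutate(name = NA_character_, role = role) |>
    select("chrom", "start", "end", "name", "role")
}

# running max of previous ends; first element -Inf so the first interval
# always opens a group. Abutting (start == prev end) stays in the group.
cummax_lag_end <- function(end) {
  if (length(end) == 0) return(numeric())
  c(-Inf, cummax(end)[-length(end)])
}

#' Total bases covered by a region set
#' @param x Region tibble.
#' @return Number of distinct bases covered.
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

#' Per-chromosome complement of a mask
#'
#' @param mask Region tibble of masked intervals.
#' @param chrom_sizes Tibble with columns `chrom`, `size`.
#' @return Region tibble covering every base not in `mask`.
#' @export
interval_complement <- function(mask, chrom_sizes) {
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  m <- merge_intervals(mask)
  out <- purrr::map(seq_len(nrow(chrom_sizes)), function(i) {
    chrom <- chrom_sizes$chrom[i]
    size <- chrom_sizes$size[i]
    mi <- m[m$chrom == chrom, , drop = FALSE]
    if (nrow(mi) > 0 && any(mi$end > size)) {
      abort(sprintf("mask interval exceeds length of %s", chrom))
    }
    starts <- c(0, mi$end)
    ends <- c(mi$start, size)
    keep <- ends > starts
    tibble(chrom = chrom, start = starts[keep], end = ends[keep])
  }) |> list_rbind()
  out$name <- NA_character_
  out$role <- "other"
  out
}

#' Permutation-eligible genome space
#'
#' Complement of the landscape's exclusion mask (segmental duplications,
#' centromeres, telomeres, assembly gaps) over every chromosome. Errors if
#' the exclusion mask covers the whole genome.
#'
#' @param landscape A [genome_landscape()].
#' @return Region tibble of allowed segments.
#' @export
allowed_space <- function(landscape) {
  stopifnot(inherits(landscape, "genome_landscape"))
  out <- interval_complement(landscape$exclusion, landscape$chrom_sizes)
  if (nrow(out) == 0 || sum(out$end - out$start) <= 0) {
    abort("exclusion mask covers the entire genome; no allowed space left")
  }
  out
}

#' Nearest unique flanking sequence of a duplication block
#'
#' Walks outward from each edge of `block`, concatenating bases of the
#' unique mask (the complement of the landscape's duplicated-sequence
#' annotation) and skipping duplicated sequence, until `flank_len` unique
#' bases have been collected per side. A side is truncated -- flagged, not
#' an error -- when the chromosome end or exhausted unique space intervenes.
#'
#' @param block One-row region tibble (the duplication block).
#' @param landscape A [genome_landscape()].
#' @param flank_len Unique bases to collect on each side (default 10 kbp).
#' @return Tibble with columns `chrom`, `start`, `end`, `side`
#'   (`"left"`/`"right"`), `truncated`; one row per contiguous collected
#'   segment, possibly several per side, possibly none for a fully
#'   truncated side.
#' @export
flanking_unique <- function(block, landscape, flank_len = 10000) {
  stopifnot(inherits(landscape, "genome_landscape"))
  validate_regions(block, "block")
  stopifnot(nrow(block) == 1)
  size <- landscape$chrom_sizes$size[match(block$chrom, landscape$chrom_sizes$chrom)]
  if (is.na(size) || block$end > size) abort("block outside chromosome bounds")
  uniq <- interval_complement(landscape$sd_mask, landscape$chrom_sizes)
  uniq <- uniq[uniq$chrom == block$chrom, , drop = FALSE]

  collect <- function(side) {
    if (side == "left") {
      segs <- uniq |> filter(.data$start < block$start) |>
        mutate(end = pmin(.data$end, block$start)) |>
        arrange(dplyr::desc(.data$end))
    } else {
      segs <- uniq |> filter(.data$end > block$end) |>
        mutate(start = pmax(.data$start, block$end)) |>
        arrange(.data$start)
    }
    got <- 0
    rows <- list()
    for (i in seq_len(nrow(segs))) {
      if (got >= flank_len) break
      need <- flank_len - got
      w <- segs$end[i] - segs$start[i]
      take <- min(w, need)
      if (side == "left") {
        rows[[length(rows) + 1]] <- tibble(chrom = block$chrom,
                                           start = segs$end[i] - take,
                                           end = segs$end[i])
      } else {
        rows[[length(rows) + 1]] <- tibble(chrom = block$chrom,
                                           start = segs$start[i],
                                           end = segs$start[i] + take)
      }
      got <- got + take
    }
    out <- list_rbind(rows)
    if (nrow(out) == 0) out <- tibble(chrom = character(), start = numeric(), end = numeric())
    out$side <- rep(side, nrow(out))
    out$truncated <- rep(got < flank_len, nrow(out))
    attr(out, "collected") <- got
    out
  }

  left <- collect("left")
  right <- collect("right")
  out <- bind_rows(left, right)
  attr(out, "truncated_sides") <- c(left = isTRUE(left$truncated[1]) || nrow(left) == 0,
                                    right = isTRUE(right$truncated[1]) || nrow(right) == 0)
  out |> arrange(.data$start)
}

#' Count distinct repeat elements overlapping a region set
#'
#' An element counts once if it overlaps the region set by at least one
#' base, even when it spans two regions.
#'
#' @param regions Region tibble.
#' @param repeats Repeat annotation tibble with columns `chrom`, `start`,
#'   `end`, `repeat_class` (one of `SINE`, `LINE`, `LTR`, `DNA`, `other`)
#'   and optionally `family`.
#' @param repeat_class Class to count.
#' @return Integer count of distinct elements.
#' @export
overlap_elements <- function(regions, repeats, repeat_class) {
  repeat_class <- match.arg(repeat_class, c("SINE", "LINE", "LTR", "DNA", "other"))
  validate_regions(regions)
  hits <- overlap_hits(regions, repeats[repeats$repeat_class == repeat_class, , drop = FALSE])
  length(unique(hits$element))
}

# per-chromosome overlap join between a region tibble and an element tibble;
# returns tibble(region = row index in regions, element = row index in elems)
overlap_hits <- function(regions, elems) {
  if (nrow(regions) == 0 || nrow(elems) == 0) {
    return(tibble(region = integer(), element = integer()))
  }
  out <- lapply(intersect(unique(regions$chrom), unique(elems$chrom)), function(ch) {
    ri <- which(regions$chrom == ch)
    ei <- which(elems$chrom == ch)
    q <- IRanges::IRanges(start = regions$start[ri] + 1, end = regions$end[ri])
    s <- IRanges::IRanges(start = elems$start[ei] + 1, end = elems$end[ei])
    ov <- IRanges::findOverlaps(q, s)
    tibble(region = ri[S4Vectors::queryHits(ov)], element = ei[S4Vectors::subjectHits(ov)])
  })
  bind_rows(out)
}

#' Per-region distinct element counts
#'
#' @inheritParams overlap_elements
#' @return Integer vector, one count per row of `regions` (an element
#'   spanning two regions contributes to both rows; [overlap_elements()]
#'   gives the deduplicated total).
#' @export
overlap_counts_per_region <- function(regions, repeats, repeat_class) {
  repeat_class <- match.arg(repeat_class, c("SINE", "LINE", "LTR", "DNA", "other"))
  hits <- overlap_hits(regions, repeats[repeats$repeat_class == repeat_class, , drop = FALSE])
  as.integer(tabulate(hits$region, nbins = nrow(regions)))
}
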