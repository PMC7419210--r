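#' Genome landscape container
#'
#' Bundles everything the permutation tests and simulators need to know
#' about a genome: chromosome sizes, a windowed GC track, repeat
#' annotations, the exclusion mask removed from the permutation space
#' (segmental duplications, centromeres, telomeres, gaps) and the
#' duplicated-sequence mask whose complement defines unique sequence for
#' acceptor-flank extraction.
#'
#' @param chrom_sizes Tibble with columns `chrom`, `size` (bp).
#' @param gc Tibble with columns `chrom`, `start`, `end`, `gc` -- a
#'   per-window GC-fraction track (windows need not be equal-sized).
#' @param repeats Tibble with columns `chrom`, `start`, `end`,
#'   `repeat_class`, `family`. Classes outside
#'   `c("SINE","LINE","LTR","DNA")` are mapped to `"other"`.
#' @param exclusion Region tibble excluded from permutation placement.
#' @param sd_mask Region tibble of duplicated sequence (defaults to
#'   `exclusion`); its complement is the unique mask.
#' @return An object of class `genome_landscape`.
#' @export
genome_landscape <- function(chrom_sizes,
                             gc,
                             repeats = empty_repeats(),
                             exclusion = region_tbl(character(), numeric(), numeric()),
                             sd_mask = exclusion) {
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  stopifnot(all(c("chrom", "start", "end", "gc") %in% names(gc)))
  chrom_sizes <- as_tibble(chrom_sizes[, c("chrom", "size")])
  repeats <- normalize_repeats(repeats)
  for (nm in list(list(gc, "gc track"), list(repeats, "repeat table"),
                  list(exclusion, "exclusion mask"), list(sd_mask, "sd mask"))) {
    x <- nm[[1]]
    if (nrow(x) == 0) next
    validate_regions(x, nm[[2]])
    sz <- chrom_sizes$size[match(x$chrom, chrom_sizes$chrom)]
    if (anyNA(sz) || any(x$end > sz)) {
      abort(sprintf("%s contains intervals outside chromosome bounds", nm[[2]]))
    }
  }
  structure(
    list(chrom_sizes = chrom_sizes,
         gc = as_tibble(gc),
         repeats = repeats,
         exclusion = as_tibble(exclusion),
         sd_mask = as_tibble(sd_mask)),
    class = "genome_landscape"
  )
}

empty_repeats <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         repeat_class = character(), family = character())
}

normalize_repeats <- function(repeats) {
  repeats <- as_tibble(repeats)
  if (!"family" %in% names(repeats)) repeats$family <- NA_character_
  if (nrow(repeats) > 0) {
    known <- c("SINE", "LINE", "LTR", "DNA")
    # RepeatMasker writes dialects like "SINE/Alu" or "LINE/L1"
    base <- sub("/.*$", "", repeats$repeat_class)
    repeats$repeat_class <- ifelse(base %in% known, base, "other")
  }
  repeats
}

#' @export
print.genome_landscape <- function(x, ...) {
  cat(sprintf("<genome_landscape> %d chromosome(s), %.2f Mbp\n",
              nrow(x$chrom_sizes), sum(x$chrom_sizes$size) / 1e6))
  cat(sprintf("  gc windows: %d | repeats: %d (%s)\n",
              nrow(x$gc), nrow(x$repeats),
              paste(sprintf("%s=%d", names(table(x$repeats$repeat_class)),
                            as.integer(table(x$repeats$repeat_class))), collapse = ", ")))
  cat(sprintf("  exclusion: %.2f%% of genome\n",
              100 * covered_bases(x$exclusion) / sum(x$chrom_sizes$size)))
  invisible(x)
}

#' Read a two-column chromosome sizes file
#'
#' @param path Whitespace-delimited file: chromosome name, length in bp.
#' @return Tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- read.delim(path, header = FALSE, sep = "", col.names = c("chrom", "size"),
                  colClasses = c("character", "numeric"))
  as_tibble(x)
}

#' Read a RepeatMasker-style annotation table
#'
#' Tolerant reader for RepeatMasker `.out`-style whitespace-delimited
#' tables: up to three header lines are skipped automatically, and the
#' columns used are query sequence (5), begin (6), end (7), repeat family
#' (10) and class/family (11). Coordinates are converted to 0-based
#' half-open. Repeat classes outside the `SINE`/`LINE`/`LTR`/`DNA` set map
#' to `"other"`.
#'
#' @param path Path to the annotation table.
#' @return Repeat tibble (`chrom`, `start`, `end`, `repeat_class`, `family`).
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # drop header lines: RepeatMasker .out starts with "SW score ..." banners
  is_data <- vapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    length(f) >= 11 && !is.na(suppressWarnings(as.numeric(f[6])))
  }, logical(1))
  lines <- lines[is_data]
  if (length(lines) == 0) return(empty_repeats())
  f <- strsplit(trimws(lines), "\\s+")
  out <- tibble(
    chrom = vapply(f, `[[`, character(1), 5),
    start = as.numeric(vapply(f, `[[`, character(1), 6)) - 1, # 1-based inclusive input
    end = as.numeric(vapply(f, `[[`, character(1), 7)),
    repeat_class = vapply(f, `[[`, character(1), 11),
    family = vapply(f, `[[`, character(1), 10)
  )
  normalize_repeats(out)
}

#' Windowed GC track from a FASTA file
#'
#' @param path FASTA of chromosome sequences.
#' @param window Window size in bp.
#' @return GC tibble (`chrom`, `start`, `end`, `gc`) suitable for
#'   [genome_landscape()].
#' @export
gc_track_from_fasta <- function(path, window = 10000) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  seqs <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(seqs), paste0, character(1), collapse = ""))
  out <- imap(seqs, function(s, nm) {
    n <- nchar(s)
    starts <- seq(0, n - 1, by = window)
    ends <- pmin(starts + window, n)
    gc <- map_dbl(seq_along(starts), function(i) {
      sub <- substr(s, starts[i] + 1, ends[i])
      bases <- strsplit(sub, "", fixed = TRUE)[[1]]
      acgt <- bases %in% c("A", "C", "G", "T")
      if (!any(acgt)) return(NA_real_)
      mean(bases[acgt] %in% c("G", "C"))
    })
    tibble(chrom = nm, start = starts, end = ends, gc = gc)
  }) |> list_rbind()
  out
}

#' Mean GC of regions from a windowed track
#'
#' Overlap-weighted mean of GC windows for each region.
#'
#' @param regions Region tibble.
#' @param gc GC tibble (`chrom`, `start`, `end`, `gc`).
#' @return Numeric vector of per-region GC fractions.
#' @export
region_gc <- function(regions, gc) {
  validate_regions(regions)
  hits <- overlap_hits(regions, gc)
  if (nrow(hits) == 0) return(rep(NA_real_, nrow(regions)))
  ov_w <- pmin(regions$end[hits$region], gc$end[hits$element]) -
    pmax(regions$start[hits$region], gc$start[hits$element])
  val <- gc$gc[hits$element]
  num <- tapply(ov_w * val, hits$region, sum, na.rm = TRUE)
  den <- tapply(ov_w * !is.na(val), hits$region, sum)
  out <- rep(NA_real_, nrow(regions))
  idx <- as.integer(names(num))
  out[idx] <- as.numeric(num) / as.numeric(den)
  out
}
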