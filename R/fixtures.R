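## Packaged study tables, transcribed from the printed clone-screen and
## integration-site tables; loaders are checksummed so silent edits fail.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "dupliconevo")
  if (p == "") abort(sprintf("packaged fixture %s not found", file))
  p
}

fixture_read <- function(file, md5) {
  p <- fixture_path(file)
  got <- unname(tools::md5sum(p))
  if (!identical(got, md5)) {
    abort(sprintf("fixture %s failed its checksum (got %s)", file, got))
  }
  as_tibble(read.delim(p, sep = "\t", stringsAsFactors = FALSE))
}

#' Clone-library hybridization screen table
#'
#' Copy-number screen of eleven primate genomic BAC libraries: positively
#' hybridizing clone counts, library fold-coverage bounds, and the
#' reported copy number per lineage. Loading is deterministic and the file
#' is verified against its checksum.
#'
#' @return Tibble with columns `lineage`, `library`, `coverage_lo`,
#'   `coverage_hi`, `n_clones`, `copy_number_reported`, `note`.
#' @export
lcr16a_clone_screen <- function() {
  fixture_read("clone_screen.tsv", "974762ba67de9e9a80d100472b7d80a0")
}

#' Pre-integration site composition table
#'
#' Fourteen duplication integration sites across primate lineages with
#' breakpoint anchors on the outgroup assembly, the printed deletion at
#' the pre-integration site (kbp; 0 = precise integration, `NA` = not
#' assessed), the composition of the deleted span, the size of the
#' inserted duplication, and a note flagging the one row confounded by a
#' cytogenetic rearrangement between chromosomes (13 analyzable loci
#' remain). For a few rows the printed anchor span does not exactly
#' reproduce the printed deletion size; the printed deletion values are
#' authoritative here and the residuals can be recomputed with
#' [pre_integration_deletion()].
#'
#' @return Tibble with columns `species`, `build`, `chrom`,
#'   `anchor_start`, `anchor_end`, `deletion_kbp`, `repeat_pct`,
#'   `ltr_pct`, `line_pct`, `sine_pct`, `unique_pct`, `insertion_kbp`,
#'   `note`.
#' @export
lcr16a_integration_sites <- function() {
  fixture_read("integration_sites.tsv", "ccfdf1683d1b7397114d346af2d5d136")
}

#' Both packaged study tables
#'
#' @return Named list with `clone_screen` and `integration_sites`.
#' @export
table_fixtures <- function() {
  list(clone_screen = lcr16a_clone_screen(),
       integration_sites = lcr16a_integration_sites())
}
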