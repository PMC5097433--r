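#' Write a simulated fixture to disk and read it back
#'
#' `write_fixture()` serialises a simulated data set to plain-text files:
#' one protein FASTA per species, a gene-info TSV (`gene_id`, `species`,
#' `cds_length_nt`), one count TSV per table (`gene_id`, `t0` ... `t4`),
#' a GAF-like annotation TSV (`gene_id`, `term_id`), an ontology edge TSV
#' (`child_term`, `parent_term`) and a truth JSON. The `read_*` helpers
#' round-trip each piece losslessly.
#'
#' @param catalogue gene catalogue tibble ([simulate_families()]).
#' @param counts named list of count tibbles ([simulate_counts()]).
#' @param truth truth list ([simulate_families()]).
#' @param out_dir output directory (created if needed).
#' @param annotations optional annotation tibble ([simulate_annotations()]).
#' @param ontology optional ontology edge tibble ([sim_ontology()]).
#' @return invisibly, the character vector of files written.
#' @export
write_fixture <- function(catalogue, counts, truth, out_dir,
                          annotations = NULL, ontology = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to output directory: ", out_dir, call. = FALSE)
  files <- character(0)
  w <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    files <<- c(files, path)
  }
  w(dplyr::select(catalogue, "gene_id", "species", "cds_length_nt"),
    "gene_info.tsv")
  for (sp in SPECIES) {
    path <- file.path(out_dir, sprintf("proteins_%s.fasta", sp))
    sub <- catalogue[catalogue$species == sp, ]
    aa <- Biostrings::AAStringSet(setNames(sub$protein, sub$gene_id))
    Biostrings::writeXStringSet(aa, path)
    files <- c(files, path)
  }
  for (nm in names(counts)) w(counts[[nm]], sprintf("counts_%s.tsv", nm))
  if (!is.null(annotations)) w(annotations, "annotations.tsv")
  if (!is.null(ontology)) w(ontology, "ontology.tsv")
  truth_path <- file.path(out_dir, "truth.json")
  truth_out <- truth
  truth_out$peak_stage <- as.list(truth_out$peak_stage) # keep gene-id keys
  jsonlite::write_json(truth_out, truth_path, auto_unbox = FALSE, digits = NA)
  files <- c(files, truth_path)
  invisible(files)
}

#' @rdname write_fixture
#' @param path file path.
#' @export
read_gene_info <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    species = readr::col_character(),
    cds_length_nt = readr::col_integer()
  ))
}

#' @rdname write_fixture
#' @export
read_stage_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_integer()
  ))
}

#' @rdname write_fixture
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(gene_id = names(aa), protein = unname(as.character(aa)))
}

#' @rdname write_fixture
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname write_fixture
#' @export
read_ontology_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname write_fixture
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$core_dev_families <- as.character(x$core_dev_families)
  x$per_species_upregulated <- lapply(x$per_species_upregulated, as.character)
  ps <- unlist(x$peak_stage)
  x$peak_stage <- if (is.null(ps)) setNames(character(0), character(0)) else ps
  x
}
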