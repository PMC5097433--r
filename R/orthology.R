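#' Protein similarity graph for ortholog-family inference
#'
#' Scores gene pairs by affine-gap Smith-Waterman local alignment
#' (match +2, mismatch -1, gap open -4, gap extend -1; a gap of length L
#' costs 4 + (L - 1)) and normalises each score by the smaller self-score,
#' `w(a, b) = S(a, b) / min(S(a, a), S(b, b))`, so weights lie in [0, 1]
#' and identical sequences get weight 1. Edges below `min_weight` are
#' dropped. Candidate pairs are pre-screened by shared 5-mers (a seeding
#' heuristic in the spirit of BLAST's word matching); set
#' `min_shared_kmers = 0` to score every pair exhaustively.
#'
#' @param catalogue tibble with at least `gene_id` and `protein`.
#' @param min_weight minimum normalised score for an edge to be kept.
#' @param min_shared_kmers minimum number of shared 5-mers for a pair to be
#'   aligned at all (0 disables the prefilter).
#' @param kmer_size word size of the prefilter.
#' @return tibble with one row per unordered pair: `gene_a`, `gene_b`
#'   (lexicographically ordered, `gene_a < gene_b`), `weight`. The graph is
#'   undirected; each edge is stored once.
#' @export
similarity_graph <- function(catalogue, min_weight = 0.25,
                             min_shared_kmers = 2, kmer_size = 5) {
  if (nrow(catalogue) == 0) stop("empty catalogue", call. = FALSE)
  if (any(is.na(catalogue$protein) | nchar(catalogue$protein) == 0))
    stop("empty protein sequence in catalogue", call. = FALSE)
  cat_sorted <- dplyr::arrange(catalogue, .data$gene_id)
  ids <- cat_sorted$gene_id
  seqs <- cat_sorted$protein
  n <- length(ids)
  if (n < 2) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          weight = double()))
  }
  if (min_shared_kmers > 0) {
    pairs <- kmer_candidate_pairs(seqs, kmer_size, min_shared_kmers)
  } else {
    pairs <- t(combn(n, 2))
  }
  if (length(pairs) == 0 || nrow(pairs) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          weight = double()))
  }
  self <- 2 * nchar(seqs) # perfect self-alignment under match = +2
  weight <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    s <- .sw_score_affine(seqs[i], seqs[j])
    s / min(self[i], self[j])
  }, numeric(1))
  tibble::tibble(gene_a = ids[pairs[, 1]], gene_b = ids[pairs[, 2]],
                 weight = weight) |>
    dplyr::filter(.data$weight >= min_weight) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

# pairs of sequence indices sharing >= min_shared distinct k-mers
kmer_candidate_pairs <- function(seqs, k, min_shared) {
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  idx <- rep(seq_along(seqs), lengths(km))
  tab <- tibble::tibble(kmer = unlist(km), i = idx)
  hits <- dplyr::inner_join(tab, tab, by = "kmer",
                            relationship = "many-to-many") |>
    dplyr::filter(.data$i.x < .data$i.y) |>
    dplyr::count(.data$i.x, .data$i.y) |>
    dplyr::filter(.data$n >= min_shared)
  cbind(hits$i.x, hits$i.y)
}

#' Markov clustering of a similarity graph into ortholog families
#'
#' Builds the column-stochastic transition matrix (self-loops set to each
#' node's maximum incident edge weight, standard MCL practice), then
#' iterates expansion (matrix squaring) and inflation (entry-wise power
#' followed by column renormalisation), pruning entries below
#' `prune_threshold`, until the maximum absolute entry change drops below
#' 1e-9 or `max_iter` is reached. Clusters are read off as connected
#' components of the attractor support; clusters with at least two members
#' are reported as families, the rest (plus genes with no edges) as
#' singletons. The procedure is deterministic: nodes are canonically sorted
#' by gene id.
#'
#' @param edges tibble from [similarity_graph()] (one row per unordered
#'   pair, or a symmetric directed listing).
#' @param catalogue optional catalogue used to attach species labels and to
#'   account for genes with no edges.
#' @param inflation inflation exponent (> 1).
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param max_iter iteration cap; non-convergence sets `converged = FALSE`.
#' @return list of class `ortholog_families`:
#'   `families` (tibble `family_id`, `gene_id`, `species`), `singletons`
#'   (tibble `gene_id`, `species`), `converged`, `n_iter`.
#' @export
mcl_cluster <- function(edges, catalogue = NULL, inflation = 2,
                        prune_threshold = 1e-5, max_iter = 100) {
  stopifnot(inflation > 1)
  if (nrow(edges) > 0) {
    # accept either one-row-per-pair or symmetric listings; reject
    # contradictory duplicates
    key <- paste(pmin(edges$gene_a, edges$gene_b),
                 pmax(edges$gene_a, edges$gene_b))
    chk <- tapply(edges$weight, key, function(w) diff(range(w)))
    if (any(chk > 1e-12))
      stop("non-symmetric edge weights", call. = FALSE)
    edges <- edges[!duplicated(key), ]
    if (any(edges$gene_a == edges$gene_b))
      edges <- edges[edges$gene_a != edges$gene_b, ]
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(nodes)
  converged <- TRUE
  n_iter <- 0L
  clusters <- list()
  if (n > 0) {
    i <- match(edges$gene_a, nodes)
    j <- match(edges$gene_b, nodes)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = rep(edges$weight, 2), dims = c(n, n))
    loop <- apply(A, 1, max)
    diag(A) <- loop
    M <- normalize_cols(A)
    repeat {
      n_iter <- n_iter + 1L
      M_new <- M %*% M
      M_new@x <- M_new@x^inflation
      M_new@x[M_new@x < prune_threshold] <- 0
      M_new <- Matrix::drop0(M_new)
      M_new <- normalize_cols(M_new)
      delta <- max(abs(M_new - M))
      M <- M_new
      if (delta < 1e-9) break
      if (n_iter >= max_iter) {
        converged <- FALSE
        warning("MCL did not converge within max_iter")
        break
      }
    }
    supp <- methods::as(M, "TsparseMatrix")
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[supp@i + 1], to = nodes[supp@j + 1]),
      directed = FALSE,
      vertices = data.frame(name = nodes)
    )
    comp <- igraph::components(g)
    clusters <- split(nodes, comp$membership)
  }
  # deterministic family ids: by decreasing size, then smallest member id
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, min, character(1)))
  clusters <- clusters[ord]
  fam <- clusters[lengths(clusters) >= 2]
  singles <- unlist(clusters[lengths(clusters) < 2], use.names = FALSE)
  families <- if (length(fam) > 0) {
    tibble::tibble(
      family_id = rep(sprintf("FAM%05d", seq_along(fam)), lengths(fam)),
      gene_id = unlist(fam, use.names = FALSE)
    )
  } else {
    tibble::tibble(family_id = character(), gene_id = character())
  }
  singletons <- tibble::tibble(gene_id = as.character(singles))
  if (!is.null(catalogue)) {
    sp <- setNames(catalogue$species, catalogue$gene_id)
    families$species <- unname(sp[families$gene_id])
    singletons <- dplyr::bind_rows(
      singletons,
      tibble::tibble(gene_id = setdiff(catalogue$gene_id,
                                       c(families$gene_id, singletons$gene_id)))
    )
    singletons$species <- unname(sp[singletons$gene_id])
  } else {
    families$species <- NA_character_
    singletons$species <- NA_character_
  }
  structure(
    list(families = families, singletons = dplyr::arrange(singletons, .data$gene_id),
         converged = converged, n_iter = n_iter),
    class = "ortholog_families"
  )
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' @export
print.ortholog_families <- function(x, ...) {
  cat(sprintf("<ortholog_families> %d families (>= 2 members), %d singletons%s\n",
              length(unique(x$families$family_id)), nrow(x$singletons),
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Family statistics
#'
#' Summarises an ortholog-family partition the way comparative genome papers
#' report it: the number of families with at least two members, the number
#' with exactly one member per species, the number present in all species,
#' and the size and per-species composition of the largest family.
#'
#' @param families tibble with `family_id`, `gene_id`, `species` (e.g. the
#'   `families` element of [mcl_cluster()] output).
#' @param species_set the species universe (defaults to the four
#'   dictyostelids DD, DL, PP, DF).
#' @return one-row tibble: `n_families_ge2`, `n_one_per_species`,
#'   `n_present_in_all`, `largest_family_size`, and a list-column
#'   `largest_family_per_species` (named integer vector).
#' @export
family_stats <- function(families, species_set = SPECIES) {
  if (nrow(families) == 0) {
    return(tibble::tibble(
      n_families_ge2 = 0L, n_one_per_species = 0L, n_present_in_all = 0L,
      largest_family_size = 0L,
      largest_family_per_species = list(setNames(integer(0), character(0)))
    ))
  }
  per <- families |>
    dplyr::count(.data$family_id, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L)
  for (sp in setdiff(species_set, names(per))) per[[sp]] <- 0L
  counts <- as.matrix(per[, species_set, drop = FALSE])
  sizes <- rowSums(counts)
  ge2 <- sizes >= 2
  largest <- which.max(sizes)
  tibble::tibble(
    n_families_ge2 = sum(ge2),
    n_one_per_species = sum(apply(counts == 1, 1, all)),
    n_present_in_all = sum(apply(counts >= 1, 1, all)),
    largest_family_size = as.integer(max(sizes)),
    largest_family_per_species = list(
      setNames(as.integer(counts[largest, ]), species_set)
    )
  )
}
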