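#' @name phylo_nomenclature
#' @title Trees, bootstrap, lineage assignment and allele nomenclature
#'
#' @description
#' Allele lineages are defined phylogenetically: a lineage is a group of
#' similar alleles that cluster together in tree analyses and are presumed
#' to descend from one ancestral allele; it is encoded as the first numeric
#' field of a standardized allele name (great apes F*01, OWM F*02, tamarin
#' F*03, marmoset F*04 with further paralogue lineages, night monkey F*05).
#' Trees are neighbor-joining on p or Jukes-Cantor distances with
#' pairwise deletion of gap/ambiguous columns; supports come from column
#' bootstrap.
NULL

#' Pairwise p or Jukes-Cantor distances from an alignment
#'
#' Columns where either sequence has a gap or ambiguity code are excluded
#' per pair (pairwise deletion); p = mismatches / compared sites, and the
#' JC transform is -(3/4) log(1 - 4p/3) (undefined for p >= 3/4).
#'
#' @param alignment named character vector of equal-length (gapped) DNA
#'   strings.
#' @param model `"p"` or `"jc"`.
#' @return object of class `dist_matrix`: list with `labels`, symmetric
#'   `matrix`, `model`.
#' @export
pairwise_distance <- function(alignment, model = c("jc", "p")) {
  model <- match.arg(model)
  n <- length(alignment)
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment sequences must be equal length")
  mat <- seq_matrix(toupper(alignment))
  okb <- matrix(mat %in% BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- okb[i, ] & okb[j, ]
    nc <- sum(use)
    if (nc == 0) stop("no comparable sites for pair ", i, ",", j)
    p <- sum(mat[i, use] != mat[j, use]) / nc
    dij <- if (model == "p") p else {
      if (p >= 0.75)
        stop("JC distance undefined for pair (", names(alignment)[i], ",",
             names(alignment)[j], "): p = ", round(p, 3), " >= 3/4")
      -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- dij
  }
  structure(list(labels = names(alignment), matrix = d, model = model),
            class = "dist_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration on the Q criterion; negative branch lengths
#' are clamped to zero. At least three taxa are required.
#'
#' @param dm a `dist_matrix` from [pairwise_distance()], or a symmetric
#'   numeric matrix with dimnames.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  m <- if (inherits(dm, "dist_matrix")) dm$matrix else as.matrix(dm)
  if (nrow(m) < 3) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Alignment columns are resampled with replacement B times; the support of
#' each internal edge is the percentage of replicate trees containing the
#' corresponding bipartition.
#'
#' @param alignment named character vector of equal-length sequences.
#' @param model distance model (`"jc"` or `"p"`).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `tree` (the NJ tree with `node.label` set to supports)
#'   and `support` (numeric per internal node, percent).
#' @export
bootstrap_support <- function(alignment, model = "jc", B = 1000, seed = 1) {
  stopifnot(B >= 1)
  tree <- nj_tree(pairwise_distance(alignment, model))
  cols <- lapply(strsplit(alignment, ""), identity)
  mat <- do.call(rbind, cols)
  rownames(mat) <- names(alignment)
  L <- ncol(mat)
  boot_trees <- with_seed(derive_seed(seed, "tree_bootstrap"), {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      sub <- apply(mat[, idx, drop = FALSE], 1, paste, collapse = "")
      nj_tree(pairwise_distance(sub, model))
    })
  })
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / B
  tree$node.label <- round(support, 1)
  list(tree = tree, support = support)
}

#' Assign a nomenclature lineage to a query allele
#'
#' The query inherits the lineage of the named references inside its
#' smallest enclosing supported clade. If that clade mixes lineages or its
#' support is below `threshold`, the query is reported as a candidate new
#' lineage together with its nearest reference.
#'
#' @param query tip label of the query in the alignment.
#' @param alignment named character vector including query and references.
#' @param reference_lineages named integer/character vector mapping
#'   reference tip labels to lineage numbers.
#' @param model,B,seed passed to [bootstrap_support()].
#' @param threshold minimum bootstrap support of the defining clade
#'   (default 70).
#' @param new_lineage_factor a query farther from its nearest reference
#'   than this multiple of the largest within-lineage reference divergence
#'   is reported as a new-lineage candidate regardless of topology
#'   (default 3; skipped when every lineage has a single reference).
#' @return list with `lineage` (number or NA), `status`
#'   (`assigned`/`new_lineage_candidate`), `support`,
#'   `nearest_reference`.
#' @export
assign_lineage <- function(query, alignment, reference_lineages,
                           model = "jc", B = 100, seed = 1,
                           threshold = 70, new_lineage_factor = 3) {
  if (!length(reference_lineages)) stop("empty reference set")
  refs <- names(reference_lineages)
  stopifnot(query %in% names(alignment), all(refs %in% names(alignment)))
  bs <- bootstrap_support(alignment, model = model, B = B, seed = seed)
  tree <- bs$tree
  support <- bs$support
  dm <- pairwise_distance(alignment, model)$matrix
  nearest <- refs[which.min(dm[query, refs])]
  # divergence guard: distance to the nearest reference must be on the
  # within-lineage scale of the reference set
  within <- unlist(lapply(split(refs, unname(reference_lineages[refs])),
                          function(g) if (length(g) >= 2) max(dm[g, g]) else NULL))
  if (length(within) && max(within) > 0 &&
      min(dm[query, refs]) > new_lineage_factor * max(within)) {
    return(list(lineage = NA, status = "new_lineage_candidate",
                support = NA_real_, nearest_reference = nearest))
  }
  # root at the reference farthest from the query so that "clades containing
  # the query" are well defined on the unrooted topology
  far <- refs[which.max(dm[query, refs])]
  rt <- ape::root(tree, outgroup = far, resolve.root = TRUE)
  qnum <- which(rt$tip.label == query)
  node <- qnum
  is_root <- function(n) !length(rt$edge[rt$edge[, 2] == n, 1])
  tiplabs <- tree$tip.label
  parts <- ape::prop.part(tree)
  node_support <- function(tips) {
    # support of the matching bipartition of the unrooted tree
    tgt <- sort(match(intersect(tips, tiplabs), tiplabs))
    comp <- sort(setdiff(seq_along(tiplabs), tgt))
    for (i in seq_along(parts)) {
      p <- sort(parts[[i]])
      if (identical(p, tgt) || identical(p, comp))
        return(unname(support[i]))
    }
    NA_real_
  }
  repeat {
    parent <- rt$edge[rt$edge[, 2] == node, 1]
    if (!length(parent)) break
    node <- parent
    tips <- ape::extract.clade(rt, node)$tip.label
    in_refs <- intersect(tips, refs)
    if (!length(in_refs)) next
    sup <- node_support(tips)
    # the smallest enclosing *supported* clade defines the lineage; keep
    # walking rootward past weakly supported nodes
    if (!is.na(sup) && sup < threshold && !is_root(node)) next
    lineages <- unique(reference_lineages[in_refs])
    if (length(lineages) == 1) {
      return(list(lineage = unname(lineages), status = "assigned",
                  support = unname(sup), nearest_reference = nearest))
    }
    return(list(lineage = NA, status = "new_lineage_candidate",
                support = unname(sup), nearest_reference = nearest))
  }
  list(lineage = NA, status = "new_lineage_candidate", support = NA_real_,
       nearest_reference = nearest)
}

#' Parse a standardized allele name
#'
#' Grammar: `Prefix-Gene*LL:AA[:SS][N]` — species prefix, gene token (`F`
#' or `F1`..`F9`), two-digit lineage, two-digit allele (allotype) number,
#' optional two-digit synonymous field, optional pseudogene suffix `N`.
#'
#' @param x character scalar, e.g. `"Mamu-F*02:04:01"`, `"Caja-F5*04:02N"`.
#' @return object of class `nomenclature_name`: list with fields
#'   `species_prefix`, `gene`, `lineage`, `allele`, `synonymous`,
#'   `pseudogene_suffix`.
#' @export
parse_name <- function(x) {
  stopifnot(length(x) == 1)
  re <- "^([A-Za-z]{2,4})-(F[0-9]?)\\*([0-9]{2}):([0-9]{2})(:([0-9]{2}))?(N)?$"
  m <- regexec(re, x)[[1]]
  if (m[1] == -1) {
    # locate the first violating position for the error message
    probe <- regexpr("^[A-Za-z]{2,4}-F[0-9]?\\*", x)
    at <- if (probe == -1) 1 else attr(probe, "match.length") + 1
    stop("malformed allele name '", x, "' (first violation near position ",
         at, ")")
  }
  g <- regmatches(x, regexec(re, x))[[1]]
  structure(list(species_prefix = g[2], gene = g[3],
                 lineage = as.integer(g[4]), allele = as.integer(g[5]),
                 synonymous = if (nzchar(g[7])) as.integer(g[7]) else NA_integer_,
                 pseudogene_suffix = g[8]),
            class = "nomenclature_name")
}

#' Format a standardized allele name
#'
#' Lossless inverse of [parse_name()].
#'
#' @param name a `nomenclature_name`.
#' @return character scalar.
#' @export
format_name <- function(name) {
  stopifnot(inherits(name, "nomenclature_name"))
  paste0(name$species_prefix, "-", name$gene, "*",
         sprintf("%02d", name$lineage), ":", sprintf("%02d", name$allele),
         if (!is.na(name$synonymous)) paste0(":", sprintf("%02d", name$synonymous)),
         name$pseudogene_suffix)
}

#' @export
print.nomenclature_name <- function(x, ...) {
  cat(format_name(x), "\n")
  invisible(x)
}
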