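#' @name deconvolution
#' @title Resolving heterozygous direct-Sanger consensus sequences
#'
#' @description
#' Direct sequencing of a diploid PCR product superimposes the two alleles:
#' heterozygous positions appear as double peaks, encoded here as two-base
#' IUPAC ambiguity codes. The resolution strategy is homozygote-first:
#' unambiguous samples seed an allele library; heterozygotes compatible with
#' a library allele (preferentially one shared with a parent or child) are
#' resolved by per-position subtraction; the procedure iterates to a fixed
#' point. Heterozygotes with two or more ambiguous positions and no anchor
#' allele are combinatorially unresolvable from peak patterns alone
#' (2^(k-1) consistent pairs) and are flagged for cloning, as are
#' length-discordant heterozygotes whose frame-offset superposition destroys
#' base identity downstream of the indel.
NULL

AMBIG_CODES <- c("M", "R", "W", "S", "Y", "K")

#' Subtract a known allele from a heterozygous consensus
#'
#' At unambiguous positions the output equals the consensus; at ambiguous
#' positions it is the encoded base that is not the known allele's base.
#' The result is deterministic and unique.
#'
#' @param consensus IUPAC consensus string (two-base codes only).
#' @param known_allele plain DNA string of equal length.
#' @return the inferred second allele (character scalar).
#' @export
subtract_allele <- function(consensus, known_allele) {
  if (nchar(consensus) != nchar(known_allele))
    stop("consensus and known allele differ in length")
  cc <- strsplit(consensus, "")[[1]]
  kk <- strsplit(known_allele, "")[[1]]
  amb <- cc %in% AMBIG_CODES
  out <- cc
  if (any(!amb & cc != kk & cc != "N"))
    stop("incompatibility: known allele mismatches consensus at an ",
         "unambiguous position (the animal does not carry this allele)")
  for (i in which(amb)) {
    pair <- IUPAC2_REV[[cc[i]]]
    if (!kk[i] %in% pair)
      stop("incompatibility: known allele base ", kk[i], " at position ", i,
           " is not encoded by ambiguity code ", cc[i])
    out[i] <- setdiff(pair, kk[i])
  }
  paste(out, collapse = "")
}

# TRUE if `allele` can be one of the two sequences underlying `consensus`
compatible_with <- function(consensus, allele) {
  if (nchar(consensus) != nchar(allele)) return(FALSE)
  cc <- strsplit(consensus, "")[[1]]
  kk <- strsplit(allele, "")[[1]]
  amb <- cc %in% AMBIG_CODES
  if (any(cc[!amb] != kk[!amb])) return(FALSE)
  all(vapply(which(amb), function(i) kk[i] %in% IUPAC2_REV[[cc[i]]], TRUE))
}

count_ambiguous <- function(consensus)
  sum(strsplit(consensus, "")[[1]] %in% AMBIG_CODES)

# relatives (parents + children) of an animal in a pedigree
pedigree_relatives <- function(pedigree, animal) {
  row <- pedigree[pedigree$animal_id == animal, ]
  parents <- stats::na.omit(c(row$sire, row$dam))
  children <- pedigree$animal_id[
    !is.na(pedigree$sire) & pedigree$sire == animal |
    !is.na(pedigree$dam) & pedigree$dam == animal]
  unique(c(as.character(parents), children))
}

#' Resolve a cohort of Sanger consensus sequences into allele pairs
#'
#' Pass 1 takes the homozygous samples (no ambiguity codes) into the allele
#' library. Pass 2 iterates to a fixed point: a heterozygote with exactly
#' one ambiguous position is split directly; one with more is resolved by
#' subtracting a compatible library allele, preferring alleles carried by a
#' resolved parent or child, and only when the resulting pair is unique.
#' Remaining multi-site heterozygotes are flagged unresolved (cloning
#' required), as are all length-discordant consensi. Children sharing no
#' allele with a resolved parent are reported as pedigree conflicts.
#'
#' @param consensi data frame with columns `animal_id`, `sequence` and
#'   optionally `unreadable_from` (non-NA marks length-discordant samples).
#' @param pedigree optional data frame (`animal_id`, `sire`, `dam`).
#' @param known_allele_library optional character vector of known alleles
#'   seeding the library.
#' @return list with `genotypes` (data frame animal_id/allele1/allele2/
#'   resolved_by), `unresolved` (data frame animal_id/n_ambiguous/
#'   candidate_pairs/reason), `library` (all alleles seen), `conflicts`
#'   (pedigree-incompatible animals).
#' @export
resolve_cohort <- function(consensi, pedigree = NULL,
                           known_allele_library = character(0)) {
  need_cols(consensi, c("animal_id", "sequence"), "consensi")
  if (is.null(consensi$unreadable_from))
    consensi$unreadable_from <- NA_integer_
  if (!is.null(pedigree)) pedigree_order(pedigree)   # validates acyclicity
  library <- unique(known_allele_library)
  genotypes <- list()
  state <- setNames(rep("open", nrow(consensi)), consensi$animal_id)
  # pass 1: homozygotes
  for (i in seq_len(nrow(consensi))) {
    if (!is.na(consensi$unreadable_from[i])) {
      state[i] <- "length_discordant"
      next
    }
    if (count_ambiguous(consensi$sequence[i]) == 0) {
      al <- consensi$sequence[i]
      library <- unique(c(library, al))
      genotypes[[consensi$animal_id[i]]] <-
        list(a1 = al, a2 = al, by = "homozygote")
      state[i] <- "resolved"
    }
  }
  # pass 2: iterate subtraction to a fixed point.  Pedigree-shared anchors
  # (peak-pattern comparison in related animals) are exhausted
  # before any resolution by bare library compatibility, so that a
  # coincidentally compatible allele can never pre-empt a Mendelian anchor.
  try_resolve <- function(i, mode) {
    a <- consensi$animal_id[i]
    cons <- consensi$sequence[i]
    k <- count_ambiguous(cons)
    if (k == 1) {
      pair <- IUPAC2_REV[[regmatches(cons, regexpr("[RYSWKM]", cons))]]
      a1 <- cons; a2 <- cons
      pos <- regexpr("[RYSWKM]", cons)
      substr(a1, pos, pos) <- pair[1]
      substr(a2, pos, pos) <- pair[2]
      library <<- unique(c(library, a1, a2))
      genotypes[[a]] <<- list(a1 = a1, a2 = a2, by = "single_site")
      state[i] <<- "resolved"
      return(TRUE)
    }
    anchors <- library[vapply(library, function(al)
      compatible_with(cons, al), TRUE)]
    if (mode == "pedigree") {
      if (is.null(pedigree)) return(FALSE)
      rel <- pedigree_relatives(pedigree, a)
      rel_alleles <- unlist(lapply(genotypes[rel], function(g)
        c(g$a1, g$a2)))
      anchors <- intersect(anchors, rel_alleles)
    }
    if (!length(anchors)) return(FALSE)
    pairs <- unique(lapply(anchors, function(al) {
      sort(c(al, subtract_allele(cons, al)))
    }))
    if (length(pairs) != 1) return(FALSE)   # ambiguous: leave for later
    a1 <- pairs[[1]][1]; a2 <- pairs[[1]][2]
    library <<- unique(c(library, a1, a2))
    genotypes[[a]] <<- list(a1 = a1, a2 = a2,
                            by = if (mode == "pedigree")
                              "subtraction_pedigree" else "subtraction")
    state[i] <<- "resolved"
    TRUE
  }
  repeat {
    # exhaust pedigree-anchored (and single-site) resolutions first
    repeat {
      progressed <- FALSE
      for (i in which(state == "open"))
        if (try_resolve(i, "pedigree")) progressed <- TRUE
      if (!progressed) break
    }
    # then at most one round of direct-compatibility resolutions
    progressed <- FALSE
    for (i in which(state == "open"))
      if (try_resolve(i, "direct")) progressed <- TRUE
    if (!progressed) break
  }
  unresolved <- do.call(rbind, lapply(which(state != "resolved"), function(i) {
    k <- count_ambiguous(consensi$sequence[i])
    reason <- if (state[i] == "length_discordant")
      "length_discordant_heterozygote"
    else if (length(library) &&
             any(vapply(library, function(al)
               compatible_with(consensi$sequence[i], al), TRUE)))
      "ambiguous_anchor" else "no_anchor"
    data.frame(animal_id = consensi$animal_id[i], n_ambiguous = k,
               candidate_pairs = if (k >= 1) 2^(k - 1) else NA_real_,
               reason = reason, stringsAsFactors = FALSE)
  }))
  gt <- do.call(rbind, lapply(names(genotypes), function(a)
    data.frame(animal_id = a, allele1 = genotypes[[a]]$a1,
               allele2 = genotypes[[a]]$a2, resolved_by = genotypes[[a]]$by,
               stringsAsFactors = FALSE)))
  # pedigree consistency check on resolved genotypes
  conflicts <- character(0)
  if (!is.null(pedigree) && !is.null(gt)) {
    for (a in gt$animal_id) {
      row <- pedigree[pedigree$animal_id == a, ]
      if (!nrow(row)) next
      for (p in stats::na.omit(c(row$sire, row$dam))) {
        if (is.null(genotypes[[p]])) next
        ga <- c(genotypes[[a]]$a1, genotypes[[a]]$a2)
        gp <- c(genotypes[[p]]$a1, genotypes[[p]]$a2)
        if (!length(intersect(ga, gp))) conflicts <- c(conflicts, a)
      }
    }
  }
  list(genotypes = gt,
       unresolved = unresolved %||%
         data.frame(animal_id = character(0), n_ambiguous = integer(0),
                    candidate_pairs = numeric(0), reason = character(0)),
       library = library, conflicts = unique(conflicts))
}
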