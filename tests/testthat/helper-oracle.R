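# Independent oracles used to check the package's own implementations.
# They deliberately share no code with the package internals: translation
# goes through seqinr and the pathway enumeration is an explicit recursion.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

oracle_translate <- function(codon)
  seqinr::translate(strsplit(codon, "")[[1]])

# brute-force pathway-averaged (sd, nd) for a sense-codon pair
oracle_pair_subs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- list()
  rec <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- c(sd, nd)
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      p <- remaining[i]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% ORACLE_STOPS && nxt != c2) next
      syn <- oracle_translate(cur) == oracle_translate(nxt)
      rec(nxt, remaining[-i], sd + syn, nd + !syn)
    }
  }
  rec(c1, pos, 0, 0)
  if (!length(paths)) {
    # all pathways blocked: unrestricted enumeration
    rec2 <- function(cur, remaining, sd, nd) {
      if (!length(remaining)) {
        paths[[length(paths) + 1]] <<- c(sd, nd)
        return(invisible())
      }
      for (i in seq_along(remaining)) {
        p <- remaining[i]
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        syn <- oracle_translate(cur) == oracle_translate(nxt)
        rec2(nxt, remaining[-i], sd + syn, nd + !syn)
      }
    }
    rec2(c1, pos, 0, 0)
  }
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# synonymous-site count of one codon (stop-target changes dropped from the
# denominator), via seqinr
oracle_codon_sites <- function(codon) {
  aa <- oracle_translate(codon)
  tot <- 0
  for (pos in 1:3) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
    neigh <- vapply(alt, function(b) {
      x <- codon; substr(x, pos, pos) <- b; x
    }, "")
    ok <- !(neigh %in% ORACLE_STOPS)
    if (!any(ok)) next
    tot <- tot + mean(vapply(neigh[ok], oracle_translate, "") == aa)
  }
  tot
}

sense_codons <- function() {
  all <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                           c("A","C","G","T")), 1, paste, collapse = "")
  setdiff(all, ORACLE_STOPS)
}

# random sense-codon sequence of n codons
random_codon_seq <- function(n, codons = sense_codons())
  paste(sample(codons, n, replace = TRUE), collapse = "")

# random additive distance matrix from a random tree, plus the tree
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = ape::unroot(tr), matrix = ape::cophenetic.phylo(tr))
}

# chain-soundness of Sanger resolutions: homozygote / single-site calls are
# logically forced; a pedigree-anchored subtraction is sound when every
# resolved relative it could have drawn its anchor from is itself sound
ped_relatives_of <- function(ped, a) {
  row <- ped[ped$animal_id == a, ]
  kids <- ped$animal_id[(!is.na(ped$sire) & ped$sire == a) |
                        (!is.na(ped$dam) & ped$dam == a)]
  unique(c(stats::na.omit(c(row$sire, row$dam)), kids))
}
chain_sound_resolutions <- function(gt, ped) {
  sound <- setNames(gt$resolved_by %in% c("homozygote", "single_site"),
                    gt$animal_id)
  repeat {
    changed <- FALSE
    for (j in which(!sound & gt$resolved_by == "subtraction_pedigree")) {
      rel <- intersect(ped_relatives_of(ped, gt$animal_id[j]), gt$animal_id)
      if (length(rel) && all(sound[rel])) {
        sound[gt$animal_id[j]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sound
}

# one standard small cohort for reuse across tests
make_test_repertoire <- function(seed = 1, allele_count = 6,
                                 clade = "owm", code = "Mamu", ...) {
  generate_repertoire(species_profile(code, clade,
                                      allele_count = allele_count,
                                      seed = seed, ...))
}
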