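#' Define a species simulation profile
#'
#' A profile captures the genetic architecture of an F-gene repertoire in one
#' primate species: number of F genes per haplotype (one in most species, a
#' duplicated region in the marmoset), allele count, point-mutation
#' polymorphism between alleles, the purifying-selection regime (dN/dS
#' target < 1), clade-default structural variants, pseudogene fraction among
#' paralogues, and bone-marrow chimerism (Callitrichidae only).
#'
#' @param species_code 4-letter taxon prefix, e.g. `"Mamu"`, `"Caja"`.
#' @param clade one of `"great_ape"`, `"owm"`, `"nwm_tamarin"`,
#'   `"nwm_nightmonkey"`, `"nwm_marmoset"`.
#' @param n_f_genes_per_haplotype integer >= 1.
#' @param allele_count total alleles in the species repertoire (>=
#'   `n_f_genes_per_haplotype`).
#' @param point_mutation_rate substitutions/site separating an allele from
#'   its gene ancestor.
#' @param dnds_target target dN/dS (< 1 for the documented purifying regime;
#'   set `allow_nonpurifying = TRUE` to override).
#' @param pseudogene_fraction fraction of paralogous genes carrying ORF
#'   disruptions (frameshift or premature stop).
#' @param chimerism logical; only allowed for the Callitrichid clades
#'   (`nwm_marmoset`, `nwm_tamarin`).
#' @param gene_divergence substitutions/site separating paralogous gene
#'   ancestors from the clade reference.
#' @param seed integer; single PRNG seed driving all repertoire draws.
#' @param allow_nonpurifying logical override for `dnds_target >= 1`.
#' @return object of class `species_profile`.
#' @export
species_profile <- function(species_code, clade,
                            n_f_genes_per_haplotype = 1L,
                            allele_count = 5L,
                            point_mutation_rate = 0.005,
                            dnds_target = 0.3,
                            pseudogene_fraction = 0,
                            chimerism = FALSE,
                            gene_divergence = 0.08,
                            seed = 1L,
                            allow_nonpurifying = FALSE) {
  clade <- match.arg(clade, CLADES)
  stopifnot(allele_count >= 1, n_f_genes_per_haplotype >= 1,
            pseudogene_fraction >= 0, pseudogene_fraction <= 1,
            point_mutation_rate >= 0)
  if (allele_count < n_f_genes_per_haplotype)
    stop("allele_count must be >= n_f_genes_per_haplotype")
  if (chimerism && !clade %in% c("nwm_marmoset", "nwm_tamarin"))
    stop("chimerism is a Callitrichid (marmoset/tamarin) feature")
  if (dnds_target >= 1 && !allow_nonpurifying)
    stop("dnds_target >= 1 rejected: F orthologues of this clade are under ",
         "purifying selection (set allow_nonpurifying = TRUE to override)")
  structure(list(species_code = species_code, clade = clade,
                 n_f_genes_per_haplotype = as.integer(n_f_genes_per_haplotype),
                 allele_count = as.integer(allele_count),
                 point_mutation_rate = point_mutation_rate,
                 dnds_target = dnds_target,
                 pseudogene_fraction = pseudogene_fraction,
                 chimerism = chimerism,
                 gene_divergence = gene_divergence,
                 seed = as.integer(seed)),
            class = "species_profile")
}

# point substitutions with synonymous bias.  Candidate substitutions are
# uniform over sites and bases; nonsynonymous candidates are accepted with
# probability dnds_target (synonymous always), which makes the post-hoc
# Nei-Gojobori ratio of the repertoire land near the target.  dnds_target =
# NA disables selection (pseudogene regime: everything accepted, stops
# allowed).
mutate_sequence <- function(seq, n_mut, dnds_target = 0.3,
                            forbid_stop = TRUE) {
  if (n_mut == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  gc <- Biostrings::GENETIC_CODE
  applied <- 0L
  attempts <- 0L
  max_attempts <- 200L * n_mut + 2000L
  while (applied < n_mut && attempts < max_attempts) {
    attempts <- attempts + 1L
    pos <- sample.int(L, 1)
    old <- chars[pos]
    new <- sample(BASES[BASES != old], 1)
    if (is.na(dnds_target)) {
      chars[pos] <- new
      applied <- applied + 1L
      next
    }
    ci <- (pos - 1L) %/% 3L
    cstart <- ci * 3L + 1L
    old_codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
    new_codon <- old_codon
    substr(new_codon, pos - cstart + 1L, pos - cstart + 1L) <- new
    if (forbid_stop && new_codon %in% STOP_CODONS) next
    if (pos <= 3L) next                      # keep the initiator codon
    syn <- identical(unname(gc[old_codon]), unname(gc[new_codon]))
    if (!syn && runif(1) > dnds_target) next
    chars[pos] <- new
    applied <- applied + 1L
  }
  paste(chars, collapse = "")
}

# ORF-disrupting lesion applied to a pseudogene ancestor: a frameshifting
# 1-nt deletion in exon 3 or a premature stop substitution in exon 4
# (alternating by gene index), mirroring the lesion classes seen in the
# marmoset paralogues.
disrupt_orf <- function(seq, exon_map, style = c("frameshift", "stop")) {
  style <- match.arg(style)
  em <- exon_map
  if (style == "frameshift") {
    e3 <- em[em$exon == "3", ]
    at <- e3$start + 50L
    list(seq = paste0(substr(seq, 1, at - 1), substring(seq, at + 1)),
         event = data.frame(kind = "frameshift_del", start = at, end = at,
                            size = 1L, exon = "3", stringsAsFactors = FALSE))
  } else {
    e4 <- em[em$exon == "4", ]
    at <- e4$start + 60L                     # codon boundary inside exon 4
    stopifnot((at - 1L) %% 3L == 0L)
    list(seq = paste0(substr(seq, 1, at - 1), "TAA", substring(seq, at + 3)),
         event = data.frame(kind = "premature_stop", start = at, end = at + 2L,
                            size = 3L, exon = "4", stringsAsFactors = FALSE))
  }
}

#' Generate a species allele repertoire with its truth table
#'
#' Alleles derive from one ancestral CDS per gene by point mutations at the
#' profile rate, with synonymous changes favoured so that the repertoire's
#' Nei-Gojobori ratio lands near `dnds_target`. Clade structural variants
#' are applied to all alleles; pseudogene paralogues carry a frameshift or
#' premature stop and an "N"-suffixed name; exon 7 is absent from every CDS.
#'
#' @param profile a [species_profile()].
#' @return object of class `mhcf_repertoire`: list with `alleles` (data
#'   frame: allele_id, name, gene, lineage, functional, sequence), `truth`
#'   (per-allele events vs the great-ape-style reference), `exon_map`,
#'   `reference` (clade reference), `profile`.
#' @export
generate_repertoire <- function(profile) {
  stopifnot(inherits(profile, "species_profile"))
  ref <- mhcf_reference(profile$clade)
  L <- nchar(ref$seq)
  n_genes <- profile$n_f_genes_per_haplotype
  with_seed(profile$seed, {
    gene_names <- if (n_genes == 1) "F" else paste0("F", seq_len(n_genes))
    lineages <- if (n_genes == 1) {
      CLADE_LINEAGE[profile$clade]
    } else if (profile$clade == "nwm_marmoset") {
      c(CLADE_LINEAGE["nwm_marmoset"],
        MARMOSET_EXTRA_LINEAGES[seq_len(n_genes - 1)])
    } else {
      rep(CLADE_LINEAGE[profile$clade], n_genes)
    }
    n_pseudo <- round(profile$pseudogene_fraction * n_genes)
    pseudo <- rep(FALSE, n_genes)
    if (n_pseudo > 0) pseudo[seq(n_genes, by = -1, length.out = n_pseudo)] <- TRUE
    # paralogous gene ancestors
    anc <- character(n_genes)
    anc[1] <- ref$seq
    if (n_genes > 1)
      for (g in 2:n_genes)
        anc[g] <- mutate_sequence(ref$seq,
                                  rpois(1, profile$gene_divergence * L),
                                  dnds_target = 0.7)
    gene_events <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      if (pseudo[g]) {
        d <- disrupt_orf(anc[g], ref$exon_map,
                         style = if (g %% 2 == 0) "frameshift" else "stop")
        anc[g] <- d$seq
        gene_events[[g]] <- d$event
      }
    }
    # allele counts per gene (as even as possible, first genes get the extra)
    per_gene <- rep(profile$allele_count %/% n_genes, n_genes)
    extra <- profile$allele_count %% n_genes
    if (extra > 0) per_gene[seq_len(extra)] <- per_gene[seq_len(extra)] + 1L
    rows <- list()
    for (g in seq_len(n_genes)) {
      seqs <- character(per_gene[g])
      seqs[1] <- anc[g]
      if (per_gene[g] > 1) {
        for (a in 2:per_gene[g]) {
          for (try in 1:100) {
            n_mut <- max(1L, rpois(1, profile$point_mutation_rate * L))
            cand <- mutate_sequence(
              anc[g], n_mut,
              dnds_target = if (pseudo[g]) NA else profile$dnds_target,
              forbid_stop = !pseudo[g])
            if (!cand %in% seqs[seq_len(a - 1)]) break
          }
          seqs[a] <- cand
        }
      }
      suffix <- if (pseudo[g]) "N" else ""
      name <- if (n_genes == 1)
        sprintf("%s-F*%02d:%02d%s", profile$species_code, lineages[g],
                seq_len(per_gene[g]), suffix)
      else
        sprintf("%s-%s*%02d:%02d%s", profile$species_code, gene_names[g],
                lineages[g], seq_len(per_gene[g]), suffix)
      rows[[g]] <- data.frame(
        allele_id = sprintf("%s_%s_a%02d", profile$species_code,
                            gene_names[g], seq_len(per_gene[g])),
        name = name, gene = gene_names[g], lineage = unname(lineages[g]),
        functional = !pseudo[g], sequence = seqs,
        stringsAsFactors = FALSE)
    }
    alleles <- do.call(rbind, rows)
    rownames(alleles) <- NULL
    # truth events vs the great-ape-style reference: clade variants shared by
    # every allele, plus per-gene ORF disruptions
    clade_ev <- if (length(ref$variants)) data.frame(
      kind = vapply(ref$variants, `[[`, "", "kind"),
      id = vapply(ref$variants, `[[`, "", "id"),
      exon = vapply(ref$variants, `[[`, "", "exon"),
      size = vapply(ref$variants, `[[`, 0L, "size"),
      stringsAsFactors = FALSE) else
      data.frame(kind = character(0), id = character(0),
                 exon = character(0), size = integer(0))
    truth <- list(clade_variants = clade_ev,
                  gene_disruptions = setNames(gene_events, gene_names),
                  pseudogene_genes = gene_names[pseudo])
    structure(list(alleles = alleles, truth = truth,
                   exon_map = ref$exon_map, reference = ref,
                   profile = profile),
              class = "mhcf_repertoire")
  })
}

#' @export
print.mhcf_repertoire <- function(x, ...) {
  cat(sprintf("mhcf_repertoire: %s (%s), %d alleles over %d gene(s), %d pseudogene gene(s)\n",
              x$profile$species_code, x$profile$clade, nrow(x$alleles),
              length(unique(x$alleles$gene)),
              length(x$truth$pseudogene_genes)))
  invisible(x)
}

# topological order of a pedigree; errors on cycles
pedigree_order <- function(ped) {
  need_cols(ped, c("animal_id", "sire", "dam"), "pedigree")
  done <- character(0)
  todo <- ped$animal_id
  while (length(todo)) {
    ready <- vapply(todo, function(a) {
      p <- ped[ped$animal_id == a, ]
      ok <- function(x) is.na(x) || x %in% done || !x %in% ped$animal_id
      ok(p$sire) && ok(p$dam)
    }, TRUE)
    if (!any(ready)) stop("pedigree contains a cycle")
    done <- c(done, todo[ready])
    todo <- todo[!ready]
  }
  done
}

#' Generate a cohort of genotyped animals from a repertoire
#'
#' Founder haplotypes are drawn from allele frequencies (uniform per gene by
#' default); offspring inherit one haplotype from each parent (Mendelian).
#' Under Callitrichid chimerism, a fraction of animals are paired as
#' bone-marrow chimeric twins whose blood additionally exposes the twin's
#' alleles, so detectable allele counts at one gene may exceed two.
#'
#' @param repertoire a `mhcf_repertoire`.
#' @param n_animals number of animals when no pedigree is given.
#' @param pedigree optional data frame (`animal_id`, `sire`, `dam`; NA for
#'   founders). Cycles are rejected.
#' @param chimerism_rate fraction of animals with a chimeric twin (requires
#'   a chimeric profile).
#' @param seed integer seed (default derived from the profile seed).
#' @return object of class `mhcf_cohort`: `animals` (animal_id, sire, dam,
#'   twin), `haplotypes` (per animal: list of two gene->allele_id vectors),
#'   `genotypes` (long data frame animal_id/gene/allele_id/origin).
#' @export
generate_cohort <- function(repertoire, n_animals = 10,
                            pedigree = NULL, chimerism_rate = 0,
                            seed = NULL) {
  stopifnot(inherits(repertoire, "mhcf_repertoire"))
  if (nrow(repertoire$alleles) == 0) stop("empty repertoire")
  prof <- repertoire$profile
  if (chimerism_rate > 0 && !prof$chimerism)
    stop("chimerism_rate > 0 requires a chimeric profile")
  if (is.null(seed)) seed <- derive_seed(prof$seed, "cohort")
  if (is.null(pedigree)) {
    pedigree <- data.frame(animal_id = sprintf("%s%03d", prof$species_code,
                                               seq_len(n_animals)),
                           sire = NA_character_, dam = NA_character_,
                           stringsAsFactors = FALSE)
  }
  ord <- pedigree_order(pedigree)
  genes <- unique(repertoire$alleles$gene)
  by_gene <- split(repertoire$alleles$allele_id, repertoire$alleles$gene)
  with_seed(seed, {
    draw_hap <- function() {
      vapply(genes, function(g) {
        ids <- by_gene[[g]]
        if (length(ids) == 1) ids else sample(ids, 1)
      }, "")
    }
    haps <- list()
    for (a in ord) {
      row <- pedigree[pedigree$animal_id == a, ]
      get_parent_hap <- function(p) {
        if (is.na(p) || is.null(haps[[p]])) draw_hap()
        else haps[[p]][[sample.int(2, 1)]]
      }
      haps[[a]] <- list(get_parent_hap(row$sire), get_parent_hap(row$dam))
    }
    animals <- pedigree[match(ord, pedigree$animal_id), , drop = FALSE]
    animals$twin <- NA_character_
    if (chimerism_rate > 0 && nrow(animals) >= 2) {
      n_pairs <- floor(chimerism_rate * nrow(animals) / 2 + 0.5)
      n_pairs <- min(n_pairs, floor(nrow(animals) / 2))
      if (n_pairs > 0) {
        picked <- sample(animals$animal_id, 2 * n_pairs)
        for (k in seq_len(n_pairs)) {
          a1 <- picked[2 * k - 1]; a2 <- picked[2 * k]
          animals$twin[animals$animal_id == a1] <- a2
          animals$twin[animals$animal_id == a2] <- a1
        }
      }
    }
    own <- do.call(rbind, lapply(animals$animal_id, function(a) {
      al <- unique(unlist(haps[[a]]))
      g <- repertoire$alleles$gene[match(al, repertoire$alleles$allele_id)]
      data.frame(animal_id = a, gene = g, allele_id = al, origin = "own",
                 stringsAsFactors = FALSE)
    }))
    twin_rows <- do.call(rbind, lapply(which(!is.na(animals$twin)), function(i) {
      a <- animals$animal_id[i]; tw <- animals$twin[i]
      al <- setdiff(unique(unlist(haps[[tw]])),
                    unique(unlist(haps[[a]])))
      if (!length(al)) return(NULL)
      g <- repertoire$alleles$gene[match(al, repertoire$alleles$allele_id)]
      data.frame(animal_id = a, gene = g, allele_id = al, origin = "twin",
                 stringsAsFactors = FALSE)
    }))
    genotypes <- rbind(own, twin_rows)
    rownames(genotypes) <- NULL
    structure(list(animals = animals, haplotypes = haps,
                   genotypes = genotypes, species = prof$species_code),
              class = "mhcf_cohort")
  })
}

#' @export
print.mhcf_cohort <- function(x, ...) {
  cat(sprintf("mhcf_cohort: %d animals (%d with pedigree links, %d chimeric)\n",
              nrow(x$animals),
              sum(!is.na(x$animals$sire) | !is.na(x$animals$dam)),
              sum(!is.na(x$animals$twin))))
  invisible(x)
}

# iid substitution errors over whole reads
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n <- nchar(seqs)
  k <- rbinom(length(seqs), n, rate)
  idx <- which(k > 0)
  for (i in idx) {
    pos <- sample.int(n[i], k[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(BASES[BASES != b], 1), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# mutually well-separated random barcodes (Hamming >= min_dist)
make_barcodes <- function(n, length = 16L, min_dist = 5L) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 10000L) {
    guard <- guard + 1L
    cand <- paste(sample(BASES, length, replace = TRUE), collapse = "")
    if (all(vapply(out, function(b) hamming(b, cand) >= min_dist, TRUE)))
      out <- c(out, cand)
  }
  if (length(out) < n) stop("could not construct ", n, " separated barcodes")
  out
}

#' Simulate barcoded replicate amplicon reads for a cohort
#'
#' Each read is `barcode + forward primer + allele CDS +
#' revcomp(reverse primer)` with iid substitution errors; a fraction of
#' reads are PCR chimeras spliced from two of the animal's alleles at a
#' uniform breakpoint. Replicates get independent error draws (independent
#' PCRs). Read orientation is randomized.
#'
#' @param cohort a `mhcf_cohort`.
#' @param repertoire the generating `mhcf_repertoire`.
#' @param depth reads per allele per replicate (>= 1).
#' @param error_rate per-base substitution error rate (in [0, 0.05)).
#' @param chimera_rate fraction of reads that are two-allele mosaics.
#' @param n_replicates number of independent PCR replicates (default 2).
#' @param seed integer seed.
#' @return list with `reads` (data frame: read_id, replicate, sequence, plus
#'   truth columns truth_animal/truth_allele/is_chimera), `manifest`
#'   (barcode -> animal), `primers` (fwd/rev motifs).
#' @export
simulate_amplicon_reads <- function(cohort, repertoire, depth = 50,
                                    error_rate = 0.005, chimera_rate = 0,
                                    n_replicates = 2, seed = NULL) {
  stopifnot(inherits(cohort, "mhcf_cohort"),
            inherits(repertoire, "mhcf_repertoire"),
            depth >= 1, error_rate >= 0, error_rate < 0.05)
  prof <- repertoire$profile
  if (is.null(seed)) seed <- derive_seed(prof$seed, "reads")
  primers <- table1_primers(prof$clade)
  seq_of <- setNames(repertoire$alleles$sequence, repertoire$alleles$allele_id)
  with_seed(seed, {
    manifest <- data.frame(animal_id = cohort$animals$animal_id,
                           barcode = make_barcodes(nrow(cohort$animals)),
                           stringsAsFactors = FALSE)
    rc_rev <- revcomp(primers$rev)
    out <- list()
    for (rep_i in seq_len(n_replicates)) {
      for (a in cohort$animals$animal_id) {
        det <- cohort$genotypes$allele_id[cohort$genotypes$animal_id == a]
        det <- unique(det)
        bc <- manifest$barcode[manifest$animal_id == a]
        inserts <- rep(det, each = depth)
        is_chim <- rep(FALSE, length(inserts))
        if (chimera_rate > 0 && length(det) >= 2)
          is_chim <- runif(length(inserts)) < chimera_rate
        ins_seq <- unname(seq_of[inserts])
        for (ci in which(is_chim)) {
          other <- sample(setdiff(det, inserts[ci]), 1)
          s1 <- seq_of[[inserts[ci]]]; s2 <- seq_of[[other]]
          bp <- sample.int(min(nchar(s1), nchar(s2)) - 1L, 1)
          ins_seq[ci] <- paste0(substr(s1, 1, bp), substring(s2, bp + 1))
        }
        reads <- paste0(bc, primers$fwd, ins_seq, rc_rev)
        reads <- inject_errors(reads, error_rate)
        flip <- runif(length(reads)) < 0.5
        if (any(flip)) reads[flip] <- revcomp(reads[flip])
        out[[length(out) + 1]] <- data.frame(
          read_id = sprintf("%s_rep%d_r%05d", a, rep_i, seq_along(reads)),
          replicate = rep_i, sequence = reads,
          truth_animal = a, truth_allele = ifelse(is_chim, NA, inserts),
          is_chimera = is_chim, stringsAsFactors = FALSE)
      }
    }
    list(reads = do.call(rbind, out), manifest = manifest, primers = primers)
  })
}

#' Simulate a direct-Sanger consensus of a one-gene genotype
#'
#' A homozygote yields the plain sequence. A heterozygote of equal-length
#' alleles yields the per-position IUPAC superposition of the two bases. A
#' length-discordant heterozygote is readable only up to the first indel;
#' downstream positions are masked `N` and `unreadable_from` is set
#' (frame-offset peak superposition).
#'
#' @param alleles character vector of 1 or 2 allele sequences.
#' @return list with `sequence`, `unreadable_from` (NA if fully readable)
#'   and `n_ambiguous`.
#' @export
simulate_sanger_consensus <- function(alleles) {
  if (!length(alleles) %in% 1:2)
    stop("direct Sanger model accepts 1 or 2 alleles, got ", length(alleles))
  if (length(alleles) == 1 || alleles[1] == alleles[2])
    return(list(sequence = alleles[1], unreadable_from = NA_integer_,
                n_ambiguous = 0L))
  a <- alleles[1]; b <- alleles[2]
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    amb <- ca != cb
    cons <- ca
    key <- paste0(pmin(ca[amb], cb[amb]), pmax(ca[amb], cb[amb]))
    cons[amb] <- IUPAC2[key]
    return(list(sequence = paste(cons, collapse = ""),
                unreadable_from = NA_integer_, n_ambiguous = sum(amb)))
  }
  # length-discordant: readable until the first indel
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      gapOpening = 5, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  first_gap <- which(pat == "-" | sub == "-")[1]
  if (is.na(first_gap)) first_gap <- min(nchar(a), nchar(b)) + 1L
  upto <- first_gap - 1L
  ca <- strsplit(substr(a, 1, upto), "")[[1]]
  cb <- strsplit(substr(b, 1, upto), "")[[1]]
  amb <- ca != cb
  cons <- ca
  if (any(amb)) {
    key <- paste0(pmin(ca[amb], cb[amb]), pmax(ca[amb], cb[amb]))
    cons[amb] <- IUPAC2[key]
  }
  tail_n <- max(nchar(a), nchar(b)) - upto
  list(sequence = paste0(paste(cons, collapse = ""), strrep("N", tail_n)),
       unreadable_from = first_gap, n_ambiguous = sum(amb))
}

#' Direct-Sanger consensus for every animal in a cohort at one gene
#'
#' @param cohort a `mhcf_cohort`.
#' @param repertoire the generating repertoire.
#' @param gene gene label (default the first gene).
#' @return data frame: animal_id, sequence, unreadable_from, n_ambiguous.
#' @export
simulate_sanger_cohort <- function(cohort, repertoire, gene = NULL) {
  if (is.null(gene)) gene <- repertoire$alleles$gene[1]
  seq_of <- setNames(repertoire$alleles$sequence, repertoire$alleles$allele_id)
  rows <- lapply(cohort$animals$animal_id, function(a) {
    ids <- unique(cohort$genotypes$allele_id[
      cohort$genotypes$animal_id == a & cohort$genotypes$gene == gene])
    if (length(ids) > 2)
      stop("animal ", a, " exposes >2 alleles at gene ", gene,
           " (chimeric blood); direct Sanger model rejected")
    cons <- simulate_sanger_consensus(unname(seq_of[ids]))
    data.frame(animal_id = a, sequence = cons$sequence,
               unreadable_from = cons$unreadable_from,
               n_ambiguous = cons$n_ambiguous, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Catalogue of alternative-splice isoform events for a clade
#'
#' Marmoset events mirror the recurrent deletion/inclusion catalogue of the
#' duplicated Caja-F region (deletions at the start of exon 2 or exon 3,
#' junction-spanning deletions, whole-exon-5 skips, intron-1 retention, an
#' 18-nt inclusion behind exon 5); the OWM menu holds the two macaque/baboon
#' isoforms (intron-1 retention and loss of the first 52 nt of exon 2).
#' Coordinates are 1-based positions on the clade CDS.
#'
#' @param clade clade label.
#' @return data frame: event_id, kind, exon, start, end, size, seq.
#' @export
isoform_event_menu <- function(clade = "nwm_marmoset") {
  clade <- match.arg(clade, CLADES)
  em <- mhcf_reference(clade)$exon_map
  st <- function(e) em$start[em$exon == e]
  en <- function(e) em$end[em$exon == e]
  del <- function(id, exon, s, e) data.frame(
    event_id = id, kind = "deletion", exon = exon,
    start = as.integer(s), end = as.integer(e),
    size = as.integer(e - s + 1), seq = "", stringsAsFactors = FALSE)
  ins <- function(id, kind, exon, after, seq) data.frame(
    event_id = id, kind = kind, exon = exon,
    start = as.integer(after + 1), end = as.integer(after),
    size = nchar(seq), seq = seq, stringsAsFactors = FALSE)
  if (clade == "owm") {
    return(rbind(
      ins("ret_intron1_130", "intron_retention", "1", en("1"), intron1_seq(130)),
      del("del_first52_exon2", "2", st("2"), st("2") + 51)))
  }
  rbind(
    del("del_last4_exon1", "1", en("1") - 3, en("1")),
    del("del_first61_exon2", "2", st("2"), st("2") + 60),
    del("del_first118_exon2", "2", st("2"), st("2") + 117),
    del("del_63_e2e3", "2-3", en("2") - 1, en("2") + 61),
    del("del_first39_exon3", "3", st("3"), st("3") + 38),
    del("del_first63_exon3", "3", st("3"), st("3") + 62),
    del("del_first74_exon3", "3", st("3"), st("3") + 73),
    del("skip_exon5", "5", st("5"), en("5")),
    ins("ret_intron1_130", "intron_retention", "1", en("1"), intron1_seq(130)),
    ins("ret_intron1_129", "intron_retention", "1", en("1"), intron1_seq(129)),
    ins("ins18_behind_exon5", "insertion", "5", en("5"),
        with_seed(9718, paste(sample(BASES, 18, TRUE), collapse = ""))))
}

# apply a set of menu events to one allele; overlapping events rejected
apply_isoform_events <- function(allele, events) {
  if (nrow(events) == 0) return(allele)
  iv <- events[order(events$start, decreasing = TRUE), , drop = FALSE]
  dels <- events[events$kind == "deletion", , drop = FALSE]
  if (nrow(dels) > 1) {
    o <- order(dels$start)
    if (any(dels$start[o][-1] <= dels$end[o][-nrow(dels)]))
      stop("overlapping events on one transcript rejected")
  }
  out <- allele
  for (k in seq_len(nrow(iv))) {
    ev <- iv[k, ]
    if (ev$kind == "deletion") {
      out <- paste0(substr(out, 1, ev$start - 1), substring(out, ev$end + 1))
    } else {
      out <- paste0(substr(out, 1, ev$end), ev$seq, substring(out, ev$end + 1))
    }
  }
  out
}

#' Generate alternative-splice isoform transcripts of an allele
#'
#' Each selected menu event yields one transcript with the event applied;
#' the returned truth table records type, coordinates and size. Multiple
#' events can be combined on one transcript via `combine = TRUE`
#' (overlapping events rejected).
#'
#' @param allele CDS string.
#' @param events rows of [isoform_event_menu()] (empty -> the unmodified
#'   transcript).
#' @param combine apply all events to a single transcript instead of one
#'   transcript per event.
#' @return data frame: transcript_id, event_id, kind, start, end, size,
#'   sequence.
#' @export
simulate_isoforms <- function(allele, events = NULL, combine = FALSE) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(transcript_id = "iso_full", event_id = "none",
                      kind = "none", start = NA_integer_, end = NA_integer_,
                      size = 0L, sequence = allele, stringsAsFactors = FALSE))
  if (combine) {
    seq <- apply_isoform_events(allele, events)
    return(data.frame(transcript_id = "iso_multi",
                      event_id = paste(events$event_id, collapse = "+"),
                      kind = paste(events$kind, collapse = "+"),
                      start = min(events$start), end = max(events$end),
                      size = sum(events$size), sequence = seq,
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    data.frame(transcript_id = paste0("iso_", ev$event_id),
               event_id = ev$event_id, kind = ev$kind,
               start = ev$start, end = ev$end, size = ev$size,
               sequence = apply_isoform_events(allele, ev),
               stringsAsFactors = FALSE)
  }))
}
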