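# Cohort generator: repertoires, pedigrees, reads, Sanger consensus, isoforms.

test_that("profile validation enforces the documented biology", {
  expect_error(species_profile("Mamu", "owm", chimerism = TRUE), "Callitrichid")
  expect_error(species_profile("Mamu", "owm", dnds_target = 1.2), "purifying")
  expect_s3_class(species_profile("Caja", "nwm_marmoset", dnds_target = 1.2,
                                  allow_nonpurifying = TRUE),
                  "species_profile")
  expect_error(species_profile("Mamu", "owm", allele_count = 0))
  expect_error(species_profile("Caja", "nwm_marmoset",
                               n_f_genes_per_haplotype = 5, allele_count = 3),
               "allele_count")
})

test_that("zero-polymorphism limit reproduces the clade reference exactly", {
  rep <- generate_repertoire(species_profile("Gogo", "great_ape",
                                             allele_count = 1,
                                             point_mutation_rate = 0,
                                             seed = 2))
  expect_equal(nrow(rep$alleles), 1)
  expect_identical(rep$alleles$sequence, mhcf_reference("great_ape")$seq)
})

test_that("clade structural variants reproduce the cross-species exon-length pattern", {
  ga <- mhcf_reference("great_ape")$exon_map
  expect_equal(ga$length[ga$exon == "2"], 270)
  # OWM and tamarin: exon 2 six nt longer than the great-ape exon 2
  for (cl in c("owm", "nwm_tamarin")) {
    em <- mhcf_reference(cl)$exon_map
    expect_equal(em$length[em$exon == "2"], 276, info = cl)
  }
  # night monkey and marmoset additionally carry the 9-nt exon-2 deletion
  for (cl in c("nwm_nightmonkey", "nwm_marmoset")) {
    em <- mhcf_reference(cl)$exon_map
    expect_equal(em$length[em$exon == "2"], 267, info = cl)
  }
  # exon 5: NWM 4-codon deletion; marmoset/tamarin 3-codon extension;
  # night monkey a further 3-nt deletion (smallest transmembrane exon)
  e5 <- vapply(c("great_ape", "owm", "nwm_tamarin", "nwm_marmoset",
                 "nwm_nightmonkey"), function(cl) {
    em <- mhcf_reference(cl)$exon_map
    em$length[em$exon == "5"]
  }, 0)
  expect_equal(unname(e5), c(117, 117, 114, 114, 102))
  # every generated allele of an OWM repertoire carries the +6 exon 2
  rep <- make_test_repertoire(seed = 4, allele_count = 4)
  expect_true(all(nchar(rep$alleles$sequence) == 1047))
})

test_that("exon 7 is absent from every clade CDS", {
  for (cl in c("great_ape", "owm", "nwm_tamarin", "nwm_nightmonkey",
               "nwm_marmoset")) {
    em <- mhcf_reference(cl)$exon_map
    expect_false("7" %in% em$exon, info = cl)
    expect_setequal(em$exon, c("1", "2", "3", "4", "5", "6", "8"))
    expect_equal(sum(em$length), nchar(mhcf_reference(cl)$seq))
  }
})

test_that("pseudogene fraction disrupts the right number of genes with N-suffixed names", {
  prof <- species_profile("Caja", "nwm_marmoset", n_f_genes_per_haplotype = 5,
                          allele_count = 10, pseudogene_fraction = 0.6,
                          chimerism = TRUE, seed = 8)
  rep <- generate_repertoire(prof)
  expect_length(rep$truth$pseudogene_genes, 3)
  bad <- rep$alleles[!rep$alleles$functional, ]
  expect_true(all(grepl("N$", bad$name)))
  expect_false(any(grepl("N$", rep$alleles$name[rep$alleles$functional])))
  # disruptions really break the ORF
  for (s in bad$sequence)
    expect_equal(classify_orf(s)$status, "pseudogene")
  for (s in rep$alleles$sequence[rep$alleles$functional])
    expect_equal(classify_orf(s)$status, "functional")
})

test_that("repertoire generation is byte-reproducible at a fixed seed", {
  r1 <- make_test_repertoire(seed = 33, allele_count = 5)
  r2 <- make_test_repertoire(seed = 33, allele_count = 5)
  expect_identical(r1$alleles, r2$alleles)
})

test_that("offspring inherit one haplotype from each parent", {
  rep <- make_test_repertoire(seed = 12, allele_count = 8)
  ped <- data.frame(animal_id = c("s", "d", "c"),
                    sire = c(NA, NA, "s"), dam = c(NA, NA, "d"))
  coh <- generate_cohort(rep, pedigree = ped)
  g <- function(a) coh$genotypes$allele_id[coh$genotypes$animal_id == a]
  expect_true(all(g("c") %in% union(g("s"), g("d"))))
  expect_true(length(unique(g("c"))) <= 2)
})

test_that("pedigree cycles are rejected", {
  rep <- make_test_repertoire(seed = 12, allele_count = 4)
  ped <- data.frame(animal_id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA))
  expect_error(generate_cohort(rep, pedigree = ped), "cycle")
})

test_that("founder genotypes at a biallelic gene follow Hardy-Weinberg", {
  rep <- make_test_repertoire(seed = 77, allele_count = 2)
  coh <- generate_cohort(rep, n_animals = 100, seed = 5)
  het <- vapply(coh$animals$animal_id, function(a) {
    length(unique(coh$genotypes$allele_id[coh$genotypes$animal_id == a])) == 2
  }, TRUE)
  # uniform draws: P(het) = 1/2; exact binomial 99.9% band for n = 100
  band <- qbinom(c(5e-4, 1 - 5e-4), 100, 0.5)
  expect_gte(sum(het), band[1])
  expect_lte(sum(het), band[2])
})

test_that("chimeric twins can expose more than two alleles at one gene", {
  prof <- species_profile("Caja", "nwm_marmoset", allele_count = 8,
                          chimerism = TRUE, seed = 14)
  rep <- generate_repertoire(prof)
  coh <- generate_cohort(rep, n_animals = 20, chimerism_rate = 0.5, seed = 2)
  counts <- vapply(coh$animals$animal_id, function(a)
    length(unique(coh$genotypes$allele_id[coh$genotypes$animal_id == a])), 0L)
  expect_gt(max(counts), 2)
  # and chimerism is refused outside the Callitrichidae
  rep2 <- make_test_repertoire(seed = 3)
  expect_error(generate_cohort(rep2, n_animals = 4, chimerism_rate = 0.5),
               "chimeric")
})

test_that("noiseless reads trim back to exact truth alleles", {
  rep <- make_test_repertoire(seed = 19, allele_count = 4)
  coh <- generate_cohort(rep, n_animals = 4)
  sim <- simulate_amplicon_reads(coh, rep, depth = 5, error_rate = 0,
                                 chimera_rate = 0)
  tr <- trim_primers(sim$reads$sequence, sim$primers$fwd, sim$primers$rev)
  expect_false(anyNA(tr$trimmed))
  expect_true(all(tr$trimmed %in% rep$alleles$sequence))
  # trimmed read equals its recorded truth allele
  seq_of <- setNames(rep$alleles$sequence, rep$alleles$allele_id)
  expect_identical(tr$trimmed, unname(seq_of[sim$reads$truth_allele]))
})

test_that("read errors arrive at the configured substitution rate", {
  rep <- make_test_repertoire(seed = 23, allele_count = 2)
  coh <- generate_cohort(rep, n_animals = 10)
  sim <- simulate_amplicon_reads(coh, rep, depth = 40, error_rate = 0.005,
                                 chimera_rate = 0, seed = 6)
  seq_of <- setNames(rep$alleles$sequence, rep$alleles$allele_id)
  tr <- trim_primers(sim$reads$sequence, sim$primers$fwd, sim$primers$rev)
  keep <- !is.na(tr$trimmed) &
    nchar(tr$trimmed) == nchar(seq_of[sim$reads$truth_allele])
  mm <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
               tr$trimmed[keep], seq_of[sim$reads$truth_allele[keep]])
  L <- nchar(rep$alleles$sequence[1])
  expected <- 0.005 * L
  expect_lt(abs(mean(mm) - expected) / expected, 0.25)
})

test_that("chimeric reads are two-allele mosaics at the configured rate", {
  rep <- make_test_repertoire(seed = 29, allele_count = 6)
  coh <- generate_cohort(rep, n_animals = 10)
  sim <- simulate_amplicon_reads(coh, rep, depth = 30, error_rate = 0,
                                 chimera_rate = 0.1, seed = 4)
  frac <- mean(sim$reads$is_chimera)
  expect_lt(abs(frac - 0.1), 0.03)
  tr <- trim_primers(sim$reads$sequence, sim$primers$fwd, sim$primers$rev)
  chim <- which(sim$reads$is_chimera & !is.na(tr$trimmed))
  truth <- rep$alleles$sequence
  n_mosaic <- 0
  for (i in head(chim, 25)) {
    s <- tr$trimmed[i]
    if (s %in% truth) next    # breakpoint at an end collapses to a parent
    ok <- FALSE
    for (x in truth) for (y in truth)
      if (nchar(x) == nchar(s) && nchar(y) == nchar(s) &&
          mhcfkit:::is_mosaic_of(s, x, y)) ok <- TRUE
    if (ok) n_mosaic <- n_mosaic + 1
  }
  expect_gt(n_mosaic, 0)
})

test_that("Sanger consensus superimposes heterozygous bases as IUPAC codes", {
  expect_equal(simulate_sanger_consensus(c("ACGT", "ACGT"))$sequence, "ACGT")
  r <- simulate_sanger_consensus(c("ACGT", "ACAT"))
  expect_equal(r$sequence, "ACRT")
  expect_equal(r$n_ambiguous, 1)
  expect_true(is.na(r$unreadable_from))
  expect_error(simulate_sanger_consensus(c("A", "A", "A")), "1 or 2")
})

test_that("length-discordant heterozygotes are unreadable after the indel", {
  a <- "ATGCCGTTACGGAAC"
  b <- "ATGCCGTTCGGAAC"   # 1-nt deletion at position 9
  r <- simulate_sanger_consensus(c(a, b))
  expect_false(is.na(r$unreadable_from))
  expect_lte(r$unreadable_from, 10)
  expect_match(r$sequence, "N+$")
})

test_that("isoform events apply exactly and overlapping events are rejected", {
  ref <- mhcf_reference("nwm_marmoset")
  menu <- isoform_event_menu("nwm_marmoset")
  e5len <- ref$exon_map$length[ref$exon_map$exon == "5"]
  skip <- simulate_isoforms(ref$seq, menu[menu$event_id == "skip_exon5", ])
  expect_equal(nchar(skip$sequence), nchar(ref$seq) - e5len)
  ret <- simulate_isoforms(ref$seq, menu[menu$event_id == "ret_intron1_130", ])
  e1 <- ref$exon_map$end[ref$exon_map$exon == "1"]
  expect_equal(substr(ret$sequence, e1 + 1, e1 + 130),
               mhcfkit:::intron1_seq(130))
  expect_equal(nchar(ret$sequence), nchar(ref$seq) + 130)
  none <- simulate_isoforms(ref$seq, menu[0, ])
  expect_identical(none$sequence, ref$seq)
  two <- menu[menu$event_id %in% c("del_first61_exon2", "del_first118_exon2"), ]
  expect_error(simulate_isoforms(ref$seq, two, combine = TRUE), "overlap")
})

test_that("the OWM isoform menu holds the two macaque/baboon splice anomalies", {
  menu <- isoform_event_menu("owm")
  expect_setequal(menu$event_id, c("ret_intron1_130", "del_first52_exon2"))
  expect_equal(menu$size[menu$event_id == "del_first52_exon2"], 52)
})
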