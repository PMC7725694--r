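#' @name reference
#' @title Mock MHC-F reference CDS and clade structural variants
#'
#' @description
#' The package carries a fixed synthetic ("mock") F-gene coding sequence that
#' plays the role of the great-ape/human-style reference in all simulations
#' and annotations. It is a 1041-nt CDS over an 8-exon gene whose mRNA lacks
#' exon 7 (the defining feature of F among class I genes), with exon lengths
#'
#'   exon 1 = 72, exon 2 = 270, exon 3 = 276, exon 4 = 276,
#'   exon 5 = 117, exon 6 = 24, exon 8 = 6 (last codon + stop)
#'
#' so that the two macaque exon partitions used for selection analysis come
#' out at 184 codons (complete exons 2-3, after the OWM 6-nt exon-2
#' insertion) and 165 codons (exons 1-4-5-6-8).
#'
#' Clade-defining structural variants, expressed in ancestral (great-ape)
#' coordinates and all codon-aligned:
#' \itemize{
#'   \item OWM and all NWM: 6-nt insertion in exon 2 (adds an Arg + Tyr codon
#'     to the alpha-1 domain), giving a 276-nt exon 2 in OWM.
#'   \item night monkey + marmoset: 9-nt deletion in exon 2, next to the
#'     peptide-binding-site region.
#'   \item all NWM: 4-codon (12-nt) deletion in exon 5 (transmembrane).
#'   \item night monkey: additional 3-nt exon-5 deletion six codons
#'     downstream (smallest known primate transmembrane section).
#'   \item marmoset + tamarin: 3-codon (9-nt) extension at the end of exon 5.
#' }
NULL

# great-ape exon lengths; exon 7 is absent from the mRNA
GA_EXON_LEN <- c(`1` = 72, `2` = 270, `3` = 276, `4` = 276,
                 `5` = 117, `6` = 24, `8` = 6)

CLADES <- c("great_ape", "owm", "nwm_tamarin", "nwm_nightmonkey",
            "nwm_marmoset")

# clade -> default lineage number of the principal F gene (nomenclature)
CLADE_LINEAGE <- c(great_ape = 1L, owm = 2L, nwm_tamarin = 3L,
                   nwm_marmoset = 4L, nwm_nightmonkey = 5L)
# extra lineage numbers used for additional marmoset paralogues
MARMOSET_EXTRA_LINEAGES <- c(6L, 7L, 8L, 9L, 10L)

# the ancestral (great-ape template) CDS, generated once, byte-stable
ancestral_cds <- function() {
  if (!is.null(.mhcf_cache$ancestral)) return(.mhcf_cache$ancestral)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  n_codon <- sum(GA_EXON_LEN) / 3            # 347
  seq <- with_seed(20111247, {
    body <- sample(setdiff(sense, "ATG"), n_codon - 2, replace = TRUE)
    paste(c("ATG", body, "TGA"), collapse = "")
  })
  .mhcf_cache$ancestral <- seq
  seq
}

# structural variants per clade, in ancestral coordinates.
# insertions attach after `after`; deletions span anc_start..anc_end.
clade_variants <- function(clade) {
  clade <- match.arg(clade, CLADES)
  ins6  <- list(kind = "insertion", exon = "2", after = 180L,
                size = 6L,  seq = "CGGTAT", id = "ins6_exon2")
  del9  <- list(kind = "deletion",  exon = "2", anc_start = 193L,
                anc_end = 201L, size = 9L, id = "del9_exon2")
  del12 <- list(kind = "deletion",  exon = "5", anc_start = 931L,
                anc_end = 942L, size = 12L, id = "del12_exon5")
  del3  <- list(kind = "deletion",  exon = "5", anc_start = 961L,
                anc_end = 963L, size = 3L, id = "del3_exon5")
  ext9  <- list(kind = "extension", exon = "5", after = 1011L,
                size = 9L, seq = "GTGCTGGTG", id = "ext9_exon5")
  switch(clade,
    great_ape       = list(),
    owm             = list(ins6),
    nwm_tamarin     = list(ins6, del12, ext9),
    nwm_nightmonkey = list(ins6, del9, del12, del3),
    nwm_marmoset    = list(ins6, del9, del12, ext9))
}

# apply ancestral-coordinate variants to a sequence (right-to-left so
# upstream coordinates stay valid)
apply_variants <- function(seq, variants) {
  pos_key <- vapply(variants, function(v)
    if (v$kind == "deletion") v$anc_start else v$after, 0L)
  for (v in variants[order(pos_key, decreasing = TRUE)]) {
    if (v$kind == "deletion") {
      seq <- paste0(substr(seq, 1, v$anc_start - 1),
                    substring(seq, v$anc_end + 1))
    } else {
      seq <- paste0(substr(seq, 1, v$after), v$seq, substring(seq, v$after + 1))
    }
  }
  seq
}

# exon lengths for a clade after its structural variants
clade_exon_lengths <- function(clade) {
  len <- GA_EXON_LEN
  for (v in clade_variants(clade)) {
    d <- if (v$kind == "deletion") -v$size else v$size
    len[v$exon] <- len[v$exon] + d
  }
  len
}

exon_map_from_lengths <- function(len) {
  end <- cumsum(len)
  data.frame(exon = names(len),
             start = c(1L, head(end, -1) + 1L),
             end = unname(end),
             length = unname(len),
             stringsAsFactors = FALSE)
}

# fixed fraction of sites separating each clade's reference from the
# great-ape template (species divergence over ~30 My), on top of the
# structural variants; well above within-species allele polymorphism so
# that lineages are phylogenetically separable
CLADE_DIVERGENCE <- 0.03

# clade reference backbone: ancestral CDS plus clade-specific point
# substitutions (deterministic per clade), before structural variants.
# Every clade, great apes included, diverges from the unobserved common
# ancestor, so each forms a proper clade rather than a paraphyletic core.
clade_backbone <- function(clade) {
  key <- paste0("backbone_", clade)
  if (!is.null(.mhcf_cache[[key]])) return(.mhcf_cache[[key]])
  base <- ancestral_cds()
  n_mut <- round(CLADE_DIVERGENCE * nchar(base))
  seq <- with_seed(derive_seed(903817, clade),
                   mutate_sequence(base, n_mut, dnds_target = 0.5))
  .mhcf_cache[[key]] <- seq
  seq
}

#' Clade reference CDS with exon map
#'
#' @param clade one of `"great_ape"`, `"owm"`, `"nwm_tamarin"`,
#'   `"nwm_nightmonkey"`, `"nwm_marmoset"`.
#' @return An object of class `mhcf_reference`: list with `seq` (CDS string),
#'   `exon_map` (data frame exon/start/end/length), `clade`, and the list of
#'   structural `variants` relative to the great-ape template.
#' @export
mhcf_reference <- function(clade = "great_ape") {
  clade <- match.arg(clade, CLADES)
  variants <- clade_variants(clade)
  seq <- apply_variants(clade_backbone(clade), variants)
  len <- clade_exon_lengths(clade)
  stopifnot(nchar(seq) == sum(len))
  structure(list(seq = seq, exon_map = exon_map_from_lengths(len),
                 clade = clade, variants = variants),
            class = "mhcf_reference")
}

#' @export
print.mhcf_reference <- function(x, ...) {
  cat("mhcf_reference (", x$clade, "): ", nchar(x$seq), " nt CDS, exons ",
      paste(x$exon_map$exon, collapse = "/"), " (exon 7 absent)\n", sep = "")
  invisible(x)
}

# ---- master alignment coordinates across clades ---------------------------
# Master columns: ancestral positions 1..1041 plus the 6 insertion columns
# (after anc 180) and the 9 extension columns (after anc 1011).  Every clade
# CDS position maps to a unique master column, so cross-clade alignments are
# built from the known variant coordinates rather than re-estimated.
master_width <- function() sum(GA_EXON_LEN) + 6L + 9L   # 1056

# integer vector: master column of each position of the clade CDS
clade_column_map <- function(clade) {
  anc_col <- c(1:180, 187:1017, 1027:1056)      # ancestral pos -> master col
  ins_col <- 181:186
  ext_col <- 1018:1026
  cols <- anc_col
  variants <- clade_variants(clade)
  ids <- vapply(variants, `[[`, "", "id")
  del_anc <- integer(0)
  for (v in variants) if (v$kind == "deletion")
    del_anc <- c(del_anc, v$anc_start:v$anc_end)
  keep <- setdiff(seq_len(sum(GA_EXON_LEN)), del_anc)
  cols <- anc_col[keep]
  # splice in insertion columns at their ancestral anchors
  if ("ins6_exon2" %in% ids) {
    at <- sum(keep <= 180L)
    cols <- append(cols, ins_col, after = at)
  }
  if ("ext9_exon5" %in% ids) {
    at <- length(cols[cols <= 1017])
    cols <- append(cols, ext_col, after = at)
  }
  stopifnot(length(cols) == sum(clade_exon_lengths(clade)),
            !is.unsorted(cols), !anyDuplicated(cols))
  cols
}

#' Project clade sequences onto the cross-clade master alignment
#'
#' Builds a gapped alignment of sequences from (possibly) different clades
#' using the known structural-variant coordinates, without re-estimating an
#' MSA. Each input must have the exact CDS length of its clade.
#'
#' @param seqs named character vector of CDS strings.
#' @param clades character vector (recycled) of clade labels, one per
#'   sequence.
#' @return named character vector of equal-length gapped sequences.
#' @export
align_by_exon_map <- function(seqs, clades) {
  clades <- rep_len(clades, length(seqs))
  out <- vapply(seq_along(seqs), function(i) {
    cm <- clade_column_map(clades[i])
    if (nchar(seqs[i]) != length(cm))
      stop("sequence ", names(seqs)[i] %||% i, " has length ",
           nchar(seqs[i]), ", expected ", length(cm), " for clade ",
           clades[i])
    row <- rep("-", master_width())
    row[cm] <- strsplit(seqs[i], "")[[1]]
    paste(row, collapse = "")
  }, "")
  names(out) <- names(seqs)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed mock intron-1 sequences for the intron-retention isoform
# (the 130-nt event; a 129-nt variant drops the last base)
intron1_seq <- function(n = 130L) {
  if (is.null(.mhcf_cache$intron1)) {
    .mhcf_cache$intron1 <- with_seed(4410130, paste0(
      "GT", paste(sample(c("A", "C", "G", "T"), 126, replace = TRUE),
                  collapse = ""), "AG"))
  }
  substr(.mhcf_cache$intron1, 1, n)
}

# amplification/trimming primer motifs per clade group (inner F1/R1 set).
# Degenerate IUPAC positions are respected during trimming.
table1_primers <- function(clade) {
  clade <- match.arg(clade, CLADES)
  grp <- switch(clade, great_ape = "great_ape", owm = "owm", "nwm")
  switch(grp,
    great_ape = list(fwd = "CCCACGCACCCCGCGGGACTC",
                     rev = "GATATCTTGCTTCTCAGTCCC"),
    owm = list(fwd = "CTCAGATTCTCCCCAGACGCG",
               rev = "GGGGTGAAGACAYATTTGGAC"),
    nwm = list(fwd = "CTAAAGTCCCCACGCACCCACGG",
               rev = "CAGGGAKGAAGACRCATTTGGAC"))
}
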