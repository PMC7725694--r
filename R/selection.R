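#' @name selection
#' @title Nei-Gojobori dN/dS over exon partitions
#'
#' @description
#' Implements the original unweighted-pathway Nei-Gojobori method: synonymous
#' and nonsynonymous site fractions per codon from the universal genetic code
#' (substitutions that would create a stop codon are excluded from the
#' denominator), observed differences resolved by averaging over all minimal
#' substitution pathways with pathways through stop codons excluded, and the
#' Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3) for multiple hits.
#' Cohort-level summaries average dN and dS over all unordered sequence
#' pairs; standard errors come from bootstrap resampling of codon columns,
#' and the reported ratio is mean(dN)/mean(dS) (the ratio of means).
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# per-codon synonymous site count (0..3); nonsyn sites = 3 - syn.
# At each position the three alternative bases are classified; changes to
# stop codons are dropped from the denominator.
codon_sites_table <- function() {
  if (!is.null(.mhcf_cache$sites)) return(.mhcf_cache$sites)
  codons <- names(Biostrings::GENETIC_CODE)
  s <- setNames(numeric(64), codons)
  for (cd in codons) {
    if (cd %in% STOP_CODONS) { s[cd] <- NA_real_; next }
    aa <- codon_aa(cd)
    tot <- 0
    for (pos in 1:3) {
      alt <- BASES[BASES != substr(cd, pos, pos)]
      neigh <- vapply(alt, function(b) {
        x <- cd; substr(x, pos, pos) <- b; x
      }, "")
      ok <- !(neigh %in% STOP_CODONS)
      if (!any(ok)) next
      tot <- tot + sum(codon_aa(neigh[ok]) == aa) / sum(ok)
    }
    s[cd] <- tot
  }
  .mhcf_cache$sites <- s
  s
}

# hardcoded permutations of 1..k, k <= 3
.perms <- list(matrix(1L, 1, 1),
               rbind(c(1L, 2L), c(2L, 1L)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# pathway-averaged (sd, nd) for one codon pair; memoized.
# Pathways through stop codons are excluded and their weight redistributed
# over the remaining minimal pathways; if every pathway is blocked the
# unrestricted average is used (never reached for sense-codon pairs at
# biological divergences, kept for totality).
codon_pair_subs <- function(c1, c2) {
  key <- paste0(c1, c2)
  memo <- .mhcf_cache$pair_memo
  if (is.null(memo)) memo <- .mhcf_cache$pair_memo <- new.env(parent = emptyenv())
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) {
    res <- c(sd = 0, nd = 0)
    memo[[key]] <- res
    return(res)
  }
  walk <- function(order) {
    cur <- c1
    sd <- nd <- 0
    for (p in pos[order]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS && !identical(nxt, c2))
        return(NULL)                     # blocked pathway
      if (identical(codon_aa(cur), codon_aa(nxt))) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- apply(.perms[[k]], 1, walk, simplify = FALSE)
  ok <- !vapply(paths, is.null, TRUE)
  if (!any(ok)) {
    # fall back to unrestricted averaging
    paths <- apply(.perms[[k]], 1, function(order) {
      cur <- c1; sd <- nd <- 0
      for (p in pos[order]) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (identical(codon_aa(cur), codon_aa(nxt))) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }, simplify = FALSE)
    ok <- rep(TRUE, length(paths))
  }
  m <- do.call(rbind, paths[ok])
  res <- c(sd = mean(m[, 1]), nd = mean(m[, 2]))
  memo[[key]] <- res
  res
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' @param p proportion of sites differing (numeric vector).
#' @return corrected distance `-(3/4) log(1 - 4p/3)`.
#' @export
jc_correct <- function(p) {
  if (any(p >= 0.75, na.rm = TRUE))
    stop("Jukes-Cantor correction undefined: p >= 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

# TRUE for codons usable in site/difference counting
codon_clean <- function(codons) {
  grepl("^[ACGT]{3}$", codons) & !(codons %in% STOP_CODONS)
}

#' Pairwise Nei-Gojobori counts and distances
#'
#' Codon positions where either sequence has a gap, an ambiguous base or a
#' stop codon are excluded pairwise before counting.
#'
#' @param a,b codon vectors (character, 3 nt each) or CDS strings whose
#'   length is a multiple of 3.
#' @param on_saturation what to do when pS or pN reaches 3/4, where the
#'   Jukes-Cantor transform is undefined: `"error"` (default) or `"na"`
#'   (counts are still returned, the distances are NA).
#' @return list with elements `S`, `N` (average synonymous / nonsynonymous
#'   site counts), `Sd`, `Nd` (pathway-averaged observed differences), `pS`,
#'   `pN`, `dS`, `dN` (Jukes-Cantor corrected), and `codons_compared`.
#' @export
ng_pairwise <- function(a, b, on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  if (length(a) == 1L && nchar(a[1]) > 3L) a <- codon_split(a)
  if (length(b) == 1L && nchar(b[1]) > 3L) b <- codon_split(b)
  if (length(a) != length(b))
    stop("sequences differ in codon count (", length(a), " vs ", length(b), ")")
  use <- codon_clean(a) & codon_clean(b)
  a <- a[use]; b <- b[use]
  if (!length(a)) stop("no comparable codons after exclusions")
  sites <- codon_sites_table()
  S <- (sum(sites[a]) + sum(sites[b])) / 2
  N <- 3 * length(a) - S
  diffs <- which(a != b)
  sd <- nd <- 0
  for (i in diffs) {
    x <- codon_pair_subs(a[i], b[i])
    sd <- sd + x[["sd"]]
    nd <- nd + x[["nd"]]
  }
  pS <- sd / S
  pN <- nd / N
  if (S == 0 && sd > 0) stop("internal inconsistency: Sd > 0 with S = 0")
  saturated <- any(c(pS, pN) >= 0.75)
  if (saturated && on_saturation == "error")
    stop("Jukes-Cantor correction undefined: p >= 3/4 ",
         "(pS = ", round(pS, 3), ", pN = ", round(pN, 3), ")")
  list(S = S, N = N, Sd = sd, Nd = nd, pS = pS, pN = pN,
       dS = if (pS < 0.75) jc_correct(pS) else NA_real_,
       dN = if (pN < 0.75) jc_correct(pN) else NA_real_,
       codons_compared = length(a))
}

#' Extract and concatenate an exon partition as a codon alignment
#'
#' Exons are concatenated in genomic order; the reading frame must be
#' preserved across every junction (each exon of the packaged references
#' starts on a codon boundary).
#'
#' @param seqs named character vector of equal-length CDS sequences sharing
#'   one exon map.
#' @param exon_map data frame with columns `exon`, `start`, `end`.
#' @param exons character vector of exon labels, e.g. `c("2", "3")`.
#' @return object of class `codon_alignment`: list with `labels`, `codons`
#'   (matrix sequences x codon columns), `partition`, `n_codons`.
#' @export
partition_alignment <- function(seqs, exon_map, exons) {
  if (!length(exons)) stop("empty partition specification")
  exons <- as.character(exons)
  need_cols(exon_map, c("exon", "start", "end"), "exon_map")
  miss <- setdiff(exons, exon_map$exon)
  if (length(miss))
    stop("exon(s) absent from map: ", paste(miss, collapse = ", "))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be equal length (one species/gene, one exon map)")
  rows <- exon_map[match(exons, exon_map$exon), ]
  rows <- rows[order(rows$start), ]
  pieces <- lapply(seqs, function(s)
    paste(substring(s, rows$start, rows$end), collapse = ""))
  len <- nchar(pieces[[1]])
  if (len %% 3 != 0)
    stop("partition length ", len, " not divisible by 3 at junction after exon ",
         rows$exon[which(cumsum(rows$end - rows$start + 1) %% 3 != 0)[1]])
  codons <- do.call(rbind, lapply(pieces, codon_split))
  rownames(codons) <- names(seqs)
  structure(list(labels = names(seqs), codons = codons,
                 partition = paste(exons, collapse = "-"),
                 n_codons = len %/% 3L),
            class = "codon_alignment")
}

#' Mean pairwise dN and dS with codon-bootstrap standard errors
#'
#' Averages the Nei-Gojobori dN and dS over all unordered sequence pairs and
#' attaches bootstrap standard errors obtained by resampling codon columns
#' and recomputing the full mean statistic. The reported ratio is
#' mean(dN)/mean(dS); it is `NA` (undefined) when mean dS is 0.
#'
#' @param ca a `codon_alignment` from [partition_alignment()], or a named
#'   character vector of equal-length CDS strings.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap resampling.
#' @return object of class `dnds_result`.
#' @export
mean_dnds <- function(ca, B = 1000, seed = 1) {
  if (is.character(ca)) {
    codons <- do.call(rbind, lapply(ca, codon_split))
    rownames(codons) <- names(ca)
    ca <- structure(list(labels = names(ca), codons = codons,
                         partition = "all", n_codons = ncol(codons)),
                    class = "codon_alignment")
  }
  stopifnot(inherits(ca, "codon_alignment"))
  cod <- ca$codons
  nseq <- nrow(cod)
  if (nseq < 2) stop("need at least two sequences")
  C <- ncol(cod)
  sites <- codon_sites_table()
  clean <- matrix(codon_clean(cod), nrow = nseq)
  site_s <- matrix(0, nseq, C)
  site_s[clean] <- sites[cod[clean]]
  pairs <- combn(nseq, 2)
  P <- ncol(pairs)
  # per-pair per-column contributions
  ok   <- matrix(FALSE, P, C)   # column usable for the pair
  sd_m <- matrix(0, P, C)
  nd_m <- matrix(0, P, C)
  s_m  <- matrix(0, P, C)       # pair-averaged syn sites
  for (k in seq_len(P)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    u <- clean[i, ] & clean[j, ]
    ok[k, ] <- u
    s_m[k, u] <- (site_s[i, u] + site_s[j, u]) / 2
    d <- which(u & cod[i, ] != cod[j, ])
    for (cc in d) {
      x <- codon_pair_subs(cod[i, cc], cod[j, cc])
      sd_m[k, cc] <- x[["sd"]]
      nd_m[k, cc] <- x[["nd"]]
    }
  }
  stat <- function(w) {
    # w: column multiplicities (length C)
    Sw  <- s_m %*% w
    nw  <- ok %*% w
    Nw  <- 3 * nw - Sw
    Sdw <- sd_m %*% w
    Ndw <- nd_m %*% w
    pS <- as.vector(Sdw / Sw)
    pN <- as.vector(Ndw / Nw)
    pS[!is.finite(pS)] <- NA
    pN[!is.finite(pN)] <- NA
    if (any(stats::na.omit(c(pS, pN)) >= 0.75))
      return(c(dN = NA_real_, dS = NA_real_))
    c(dN = mean(-0.75 * log(1 - 4 * pN / 3), na.rm = TRUE),
      dS = mean(-0.75 * log(1 - 4 * pS / 3), na.rm = TRUE))
  }
  point <- stat(rep(1, C))
  boot <- with_seed(derive_seed(seed, "dnds_bootstrap"), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(C, C, replace = TRUE)
      stat(tabulate(idx, nbins = C))
    }, c(dN = 0, dS = 0))
  })
  ratio_boot <- boot["dN", ] / boot["dS", ]
  ratio_boot[!is.finite(ratio_boot)] <- NA
  res <- list(partition = ca$partition,
              n_codons = ca$n_codons,
              n_seqs = nseq,
              mean_dN = unname(point["dN"]),
              mean_dS = unname(point["dS"]),
              SE_dN = sd(boot["dN", ], na.rm = TRUE),
              SE_dS = sd(boot["dS", ], na.rm = TRUE),
              ratio = if (is.na(point["dS"]) || point["dS"] == 0) NA_real_
                      else unname(point["dN"] / point["dS"]),
              SE_ratio = sd(ratio_boot, na.rm = TRUE),
              B = B, seed = seed)
  class(res) <- "dnds_result"
  res
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("Nei-Gojobori dN/dS, partition exons %s (N = %d codons, %d seqs)\n",
              x$partition, x$n_codons, x$n_seqs))
  cat(sprintf("  dN = %.3f (SE %.3f)   dS = %.3f (SE %.3f)\n",
              x$mean_dN, x$SE_dN, x$mean_dS, x$SE_dS))
  if (is.na(x$ratio)) cat("  dN/dS undefined (mean dS = 0)\n")
  else cat(sprintf("  dN/dS = %.2f\n", x$ratio))
  invisible(x)
}

#' Per-partition dN/dS report over the two macaque exon partitions
#'
#' Convenience wrapper: runs [mean_dnds()] on the complete exons 2-3
#' partition and on the remaining exons 1-4-5-6-8 and returns one tidy data
#' frame.
#'
#' @param seqs named character vector of same-length CDS sequences.
#' @param exon_map exon map shared by the sequences.
#' @param B,seed bootstrap replicates and seed.
#' @return data frame with one row per partition.
#' @export
dnds_report <- function(seqs, exon_map, B = 1000, seed = 1) {
  parts <- list(`2-3` = c("2", "3"),
                `1-4-5-6-8` = c("1", "4", "5", "6", "8"))
  do.call(rbind, lapply(names(parts), function(pn) {
    r <- mean_dnds(partition_alignment(seqs, exon_map, parts[[pn]]),
                   B = B, seed = seed)
    data.frame(partition = pn, n_codons = r$n_codons, n_seqs = r$n_seqs,
               dN = r$mean_dN, SE_dN = r$SE_dN,
               dS = r$mean_dS, SE_dS = r$SE_dS,
               ratio = r$ratio, SE_ratio = r$SE_ratio,
               stringsAsFactors = FALSE)
  }))
}
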