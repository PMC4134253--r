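# Genetic diversity statistics for codominant genotype tables and aligned
# sequences: allele frequencies, observed / unbiased expected
# heterozygosity, Hardy-Weinberg exact tests, haplotype and nucleotide
# diversity.

#' Construct a genotype table
#'
#' A genotype table is a long-format data frame with one row per individual
#' x locus: columns `individual`, `locus`, `allele1`, `allele2`. Alleles are
#' opaque labels (microsatellite fragment sizes, letters, integers); a
#' missing genotype has both alleles `NA`. Half-missing rows are invalid.
#'
#' @param df Data frame with the four columns above.
#' @return The validated data frame with class `genotypes`.
#' @export
genotypes <- function(df) {
  req <- c("individual", "locus", "allele1", "allele2")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("genotype table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("genotype table is empty", call. = FALSE)
  half <- xor(is.na(df$allele1), is.na(df$allele2))
  if (any(half))
    stop("half-missing genotype (one allele recorded) at row(s): ",
         paste(utils::head(which(half), 5L), collapse = ", "), call. = FALSE)
  df$individual <- as.character(df$individual)
  df$locus <- as.character(df$locus)
  structure(as.data.frame(df), class = c("genotypes", "data.frame"))
}

check_freq_table <- function(freqs) {
  if (!is.list(freqs) || is.null(names(freqs)) || !length(freqs))
    stop("allele frequency table must be a named list of numeric vectors",
         call. = FALSE)
  for (l in names(freqs)) {
    p <- freqs[[l]]
    if (!is.numeric(p) || any(p < 0))
      stop("allele frequencies at locus ", l, " must be non-negative",
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop("allele frequencies at locus ", l, " sum to ", sum(p),
           ", not 1", call. = FALSE)
  }
  invisible(freqs)
}

#' Construct / validate an allele frequency table
#'
#' @param freqs Named list: locus -> named numeric vector of allele
#'   frequencies (each summing to 1 within 1e-9).
#' @param n Optional named vector of per-locus genotyped sample sizes.
#' @return The list with class `allele_freq_table`.
#' @export
allele_freq_table <- function(freqs, n = NULL) {
  check_freq_table(freqs)
  structure(freqs, class = "allele_freq_table", n = n)
}

#' Per-locus allele frequencies of a genotype table
#'
#' Counts allele copies among non-missing genotypes at each locus. Loci with
#' no genotyped individuals are omitted with a warning.
#'
#' @param g A [genotypes()] table.
#' @return An [allele_freq_table()] with per-locus sample sizes in
#'   `attr(, "n")`.
#' @export
allele_frequencies <- function(g) {
  g <- genotypes(g)
  loci <- unique(g$locus)
  out <- list()
  ns <- integer(0)
  for (l in loci) {
    rows <- g[g$locus == l & !is.na(g$allele1), ]
    if (nrow(rows) == 0L) {
      warning("locus ", l, " has no genotyped individuals; omitted",
              call. = FALSE)
      next
    }
    tab <- table(c(as.character(rows$allele1), as.character(rows$allele2)))
    out[[l]] <- as.numeric(tab) / sum(tab)
    names(out[[l]]) <- names(tab)
    ns[l] <- nrow(rows)
  }
  if (!length(out))
    stop("no locus with genotyped individuals", call. = FALSE)
  allele_freq_table(out, n = ns)
}

#' Mean gene diversity of an allele frequency table
#'
#' Plain expected heterozygosity `1 - sum(p^2)` per locus (no sample-size
#' correction), averaged when `mean = TRUE`; this is the quantity tracked by
#' the simulator's drift bookkeeping.
#'
#' @param freqs An [allele_freq_table()].
#' @param mean Return the across-locus mean (default) or the per-locus
#'   vector.
#' @return Numeric.
#' @export
gene_diversity <- function(freqs, mean = TRUE) {
  check_freq_table(freqs)
  he <- vapply(freqs, function(p) 1 - sum(p^2), numeric(1))
  if (mean) base::mean(he) else he
}

#' Observed and unbiased expected heterozygosity per locus
#'
#' Observed heterozygosity is the fraction of genotyped individuals that are
#' heterozygous. Expected heterozygosity is the unbiased gene diversity
#' (Nei 1978), `(2n/(2n-1)) * (1 - sum(p-hat^2))`, the convention of the
#' standard microsatellite packages. Monomorphic loci are reported with
#' `he = 0` and flagged.
#'
#' @param g A [genotypes()] table.
#' @return Data frame with columns `locus`, `n_genotyped`, `ho`, `he`
#'   (unbiased), `he_plain` and `monomorphic`.
#' @export
heterozygosity <- function(g) {
  g <- genotypes(g)
  freqs <- suppressWarnings(allele_frequencies(g))
  ns <- attr(freqs, "n")
  rows <- lapply(names(freqs), function(l) {
    sub <- g[g$locus == l & !is.na(g$allele1), ]
    n <- nrow(sub)
    p <- freqs[[l]]
    plain <- 1 - sum(p^2)
    data.frame(locus = l, n_genotyped = n,
               ho = mean(as.character(sub$allele1) !=
                           as.character(sub$allele2)),
               he = (2 * n / (2 * n - 1)) * plain,
               he_plain = plain,
               monomorphic = length(p) == 1L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# conditional log-probability of a genotype count table given its allele
# counts (Levene / Guo & Thompson):
# P = n! prod(a_i!) 2^h / ((2n)! prod(n_ij!))
hwe_log_prob <- function(het_total, log_nij_fact, n, allele_counts) {
  lgamma(n + 1) + sum(lgamma(allele_counts + 1)) + het_total * log(2) -
    lgamma(2 * n + 1) - log_nij_fact
}

# enumerate all genotype tables with the given allele counts; calls
# visit(logp) for each. Returns number of tables, or -1 if aborted after
# more than max_tables.
hwe_enumerate <- function(allele_counts, visit, max_tables = 1e6) {
  k <- length(allele_counts)
  count <- 0L
  aborted <- FALSE
  rec <- function(i, rem, het, logfact) {
    # distribute rem[i] copies of allele i among genotypes (i,i) and (i,j>i)
    if (aborted) return()
    if (i == k) {
      if (rem[k] %% 2L != 0L) return()
      nii <- rem[k] %/% 2L
      count <<- count + 1L
      if (count > max_tables) { aborted <<- TRUE; return() }
      visit(het, logfact + lgamma(nii + 1))
      return()
    }
    # heterozygote copies with alleles j > i: composition of h over k-i cells
    ri <- rem[i]
    for (nii in 0:(ri %/% 2L)) {
      h <- ri - 2L * nii # copies to pair with later alleles
      distribute(i, h, i + 1L, rem, het + h,
                 logfact + lgamma(nii + 1), nii_done = TRUE)
    }
  }
  distribute <- function(i, h, j, rem, het, logfact, nii_done) {
    if (aborted) return()
    if (j > k) {
      if (h == 0L) rec(i + 1L, rem, het, logfact)
      return()
    }
    top <- min(h, rem[j])
    for (nij in 0:top) {
      rem2 <- rem
      rem2[j] <- rem2[j] - nij
      distribute(i, h - nij, j + 1L, rem2, het,
                 logfact + lgamma(nij + 1), nii_done)
    }
  }
  rec(1L, allele_counts, 0L, 0)
  if (aborted) -1L else count
}

#' Hardy-Weinberg exact test for one locus
#'
#' Conditional exact test of Hardy-Weinberg genotype proportions given the
#' allele counts, using the probability of the genotype table as test
#' statistic (Guo & Thompson / Levene convention, not chi-square): the
#' p-value is the total conditional probability of all tables no more
#' probable than the observed one. Tables are fully enumerated when their
#' number does not exceed `max_tables`; otherwise a Monte-Carlo version with
#' `nperm` permutations of the allele list is used and the Monte-Carlo
#' standard error is attached. A monomorphic locus returns p = 1.
#'
#' @param a1,a2 Allele vectors (one entry per genotyped individual), or
#'   `a1` may be a two-column matrix/data frame of genotypes. Missing
#'   genotypes must be removed beforehand.
#' @param method `"auto"` (enumerate when feasible), `"enumeration"` or
#'   `"mc"`.
#' @param nperm Number of Monte-Carlo permutations (>= 1e5 by default).
#' @param max_tables Enumeration feasibility bound.
#' @return The p-value (in (0, 1]), with attributes `method` and (for the
#'   Monte-Carlo path) `mc_se`.
#' @examples
#' # 3 AA, 0 AB, 3 BB
#' hwe_exact_test(rep(c("A", "B"), c(3, 3)), rep(c("A", "B"), c(3, 3)))
#' @export
hwe_exact_test <- function(a1, a2 = NULL, method = c("auto", "enumeration",
                                                     "mc"),
                           nperm = 1e5, max_tables = 1e6) {
  method <- match.arg(method)
  if (is.null(a2)) {
    a1 <- as.matrix(a1)
    a2 <- a1[, 2]
    a1 <- a1[, 1]
  }
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- as.character(a1[keep]); a2 <- as.character(a2[keep])
  n <- length(a1)
  if (n < 1L) stop("no genotyped individuals", call. = FALSE)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k == 1L)
    return(structure(1.0, method = "monomorphic"))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  allele_counts <- tabulate(c(i1, i2), nbins = k)

  table_stats <- function(i1, i2) {
    lo <- pmin(i1, i2); hi <- pmax(i1, i2)
    cell <- (lo - 1L) * k + hi
    nij <- tabulate(cell, nbins = k * k)
    list(het = sum(lo != hi), logfact = sum(lgamma(nij + 1)))
  }
  obs <- table_stats(i1, i2)
  logp_obs <- hwe_log_prob(obs$het, obs$logfact, n, allele_counts)
  tol <- 1e-9

  if (method != "mc") {
    p_acc <- 0
    total <- 0
    cnt <- hwe_enumerate(allele_counts, function(het, logfact) {
      lp <- hwe_log_prob(het, logfact, n, allele_counts)
      total <<- total + exp(lp)
      if (lp <= logp_obs + tol) p_acc <<- p_acc + exp(lp)
    }, max_tables = max_tables)
    if (cnt > 0)
      return(structure(min(1, p_acc / total), method = "enumeration",
                       n_tables = cnt))
    if (method == "enumeration")
      stop("more than ", format(max_tables),
           " genotype tables; use method = 'mc'", call. = FALSE)
  }
  # Monte-Carlo: permute the 2n allele copies and re-pair
  pool <- c(i1, i2)
  hits <- 0L
  for (b in seq_len(nperm)) {
    perm <- sample(pool)
    half <- length(pool) %/% 2L
    st <- table_stats(perm[seq_len(half)], perm[half + seq_len(half)])
    lp <- hwe_log_prob(st$het, st$logfact, n, allele_counts)
    if (lp <= logp_obs + tol) hits <- hits + 1L
  }
  p <- (hits + 1) / (nperm + 1)
  structure(p, method = "mc", mc_se = sqrt(p * (1 - p) / nperm))
}

#' Hardy-Weinberg exact tests for every locus of a genotype table
#'
#' @param g A [genotypes()] table.
#' @param ... Passed to [hwe_exact_test()].
#' @return Data frame with columns `locus`, `n_genotyped`, `hwe_p`,
#'   `method`.
#' @export
hwe_test <- function(g, ...) {
  g <- genotypes(g)
  loci <- unique(g$locus)
  rows <- lapply(loci, function(l) {
    sub <- g[g$locus == l & !is.na(g$allele1), ]
    if (nrow(sub) < 2L)
      return(data.frame(locus = l, n_genotyped = nrow(sub),
                        hwe_p = NA_real_, method = "insufficient"))
    p <- hwe_exact_test(sub$allele1, sub$allele2, ...)
    data.frame(locus = l, n_genotyped = nrow(sub), hwe_p = as.numeric(p),
               method = attr(p, "method"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- sequence statistics -------------------------------------------------

# normalize input to an upper-case character matrix (rows = sequences)
as_seq_matrix <- function(seqs) {
  if (inherits(seqs, "DNAbin")) {
    if (is.list(seqs)) {
      lens <- lengths(seqs)
      if (length(unique(lens)) != 1L)
        stop("ragged alignment: sequence lengths ",
             paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
      seqs <- as.matrix(seqs)
    }
    m <- toupper(unname(as.character(seqs)))
    rownames(m) <- rownames(seqs)
    return(m)
  }
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths ",
           paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
    return(m)
  }
  if (is.matrix(seqs)) return(toupper(seqs))
  stop("unsupported sequence container", call. = FALSE)
}

valid_base <- function(m) {
  v <- m %in% c("A", "C", "G", "T")
  dim(v) <- dim(m)
  v
}

#' Haplotype diversity of an aligned sequence sample
#'
#' Haplotype (gene) diversity `Hd = n/(n-1) (1 - sum p_i^2)` over the
#' frequencies of distinct full-length haplotypes, with the sampling
#' variance of Nei (1987, eq. 8.12) for the standard error. Sequences
#' containing gaps or ambiguous bases are dropped from haplotype calling
#' (reported via message).
#'
#' @param seqs Aligned sequences: `ape::DNAbin`, character matrix, or a
#'   character vector of equal-length strings.
#' @return List with `n`, `n_haplotypes`, `hd`, `hd_se`.
#' @export
haplotype_diversity <- function(seqs) {
  m <- as_seq_matrix(seqs)
  clean <- apply(valid_base(m), 1, all)
  if (any(!clean))
    message(sum(!clean), " sequence(s) with gaps/ambiguity dropped from ",
            "haplotype calling")
  m <- m[clean, , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 unambiguous sequences", call. = FALSE)
  hap <- apply(m, 1, paste0, collapse = "")
  p <- as.numeric(table(hap)) / n
  s2 <- sum(p^2)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(n = n, n_haplotypes = length(p), hd = hd, hd_se = sqrt(max(v, 0)))
}

#' Nucleotide diversity of an aligned sequence sample
#'
#' Average proportion of differing sites over all sequence pairs, with
#' pairwise exclusion of sites where either sequence has a gap or an
#' ambiguous base: `pi = mean over pairs of d_ij / L_ij(valid)`. The
#' standard error uses the no-recombination sampling variance of Tajima
#' (1983; Nei 1987 eq. 10.9).
#'
#' @param seqs As in [haplotype_diversity()].
#' @return List with `n`, `pi`, `pi_se`, `alignment_length`.
#' @export
nucleotide_diversity <- function(seqs) {
  m <- as_seq_matrix(seqs)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  L <- ncol(m)
  ok <- valid_base(m)
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      both <- ok[i, ] & ok[j, ]
      nv <- sum(both)
      if (nv == 0L)
        stop("sequence pair (", i, ", ", j, ") shares no valid sites",
             call. = FALSE)
      tot <- tot + sum(m[i, both] != m[j, both]) / nv
    }
  }
  pi <- tot / (n * (n - 1) / 2)
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(n = n, pi = pi, pi_se = sqrt(v), alignment_length = L)
}

#' Combined sequence summary
#'
#' @param seqs As in [haplotype_diversity()].
#' @return One-row data frame: `n_sequences`, `n_haplotypes`, `hd`,
#'   `hd_se`, `pi`, `pi_se`, `alignment_length`.
#' @export
sequence_stats <- function(seqs) {
  h <- haplotype_diversity(seqs)
  p <- nucleotide_diversity(seqs)
  data.frame(n_sequences = p$n, n_haplotypes = h$n_haplotypes,
             hd = h$hd, hd_se = h$hd_se, pi = p$pi, pi_se = p$pi_se,
             alignment_length = p$alignment_length)
}
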