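# Synthetic-data generators: allele-frequency spectra matched to target
# gene diversities, Hardy-Weinberg genotype tables with missingness,
# haplotype-structured mitochondrial alignments, and line-transect sighting
# records. All generators are seed-deterministic.

#' Per-locus expected heterozygosities of the urban study population
#'
#' The printed per-locus unbiased expected heterozygosities of the
#' 13-microsatellite panel typed in the urban park population (hair samples
#' of 68 squirrels). One locus (Scv15) was monomorphic there and carries
#' `NA`; the across-locus mean of the 12 polymorphic values is 0.4745
#' (printed as 0.475).
#'
#' @param polymorphic_only Drop the monomorphic locus (default).
#' @return Named numeric vector of expected heterozygosities.
#' @export
sceaux_locus_he <- function(polymorphic_only = TRUE) {
  he <- c(Rsu3 = 0.465, Rsu4 = 0.462, Rsu5 = 0.417, Rsu6 = 0.526,
          Scv6 = 0.592, Scv8 = 0.232, Scv1 = 0.395, Scv12 = 0.230,
          Scv13 = 0.408, Scv14 = 0.627, Scv15 = NA_real_, Scv3 = 0.822,
          Scv9 = 0.518)
  if (polymorphic_only) he[!is.na(he)] else he
}

#' Per-locus genotyped sample sizes of the urban study population
#'
#' @return Named integer vector (38-65 individuals per locus).
#' @export
sceaux_locus_n <- function() {
  c(Rsu3 = 61L, Rsu4 = 48L, Rsu5 = 38L, Rsu6 = 65L, Scv6 = 54L,
    Scv8 = 47L, Scv1 = 64L, Scv12 = 55L, Scv13 = 54L, Scv14 = 64L,
    Scv15 = 52L, Scv3 = 59L, Scv9 = 46L)
}

# allele spectrum with plain gene diversity h using exactly k alleles: one
# major allele plus k-1 equifrequent minor alleles at
# p = (1 - sqrt(1 - h k/(k-1))) / k; feasible whenever h <= 1 - 1/k.
# For k = 2 the major allele is the classical two-allele solution
# (1 + sqrt(1 - 2h))/2.
spectrum_k <- function(h, k) {
  if (k == 1L) return(1)
  disc <- 1 - h * k / (k - 1)
  if (disc < 0) return(NULL)
  p <- (1 - sqrt(disc)) / k
  q <- 1 - (k - 1) * p
  c(q, rep(p, k - 1L))
}

#' Allele-frequency spectra matched to target gene diversities
#'
#' For each target expected heterozygosity h, constructs a per-locus allele
#' frequency spectrum whose plain gene diversity `1 - sum(p^2)` equals h to
#' within 1e-6. Targets of 0 give a single allele; targets up to 0.5 use the
#' analytic two-allele solution `p = (1 + sqrt(1 - 2h))/2`; larger targets
#' use the smallest allele number whose maximum diversity `1 - 1/k` covers
#' h, with an equifrequent-plus-residual spectrum. `n_alleles` can force
#' richer, microsatellite-like spectra (expected drift of gene diversity is
#' insensitive to allele number, so targets are unaffected).
#'
#' @param targets Numeric vector of target gene diversities in `[0, 1)`,
#'   optionally named by locus.
#' @param max_alleles Feasibility bound on the allele number.
#' @param n_alleles Optional fixed allele count per locus (scalar or
#'   vector); must satisfy `1 - 1/n_alleles >= target`.
#' @return An [allele_freq_table()].
#' @examples
#' freqs_from_target_he(0.5)[[1]]  # two alleles at 0.5 each
#' @export
freqs_from_target_he <- function(targets, max_alleles = 10L,
                                 n_alleles = NULL) {
  if (any(targets < 0 | targets >= 1))
    stop("target gene diversities must lie in [0, 1)", call. = FALSE)
  nm <- names(targets)
  if (is.null(nm)) nm <- sprintf("L%02d", seq_along(targets))
  if (!is.null(n_alleles))
    n_alleles <- rep_len(as.integer(n_alleles), length(targets))
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    h <- targets[i]
    if (h == 0) {
      sp <- 1
    } else if (!is.null(n_alleles)) {
      sp <- spectrum_k(h, n_alleles[i])
      if (is.null(sp))
        stop("target he = ", h, " infeasible with ", n_alleles[i],
             " alleles", call. = FALSE)
    } else {
      k <- if (h <= 0.5) 2L else ceiling(1 / (1 - h))
      sp <- spectrum_k(h, k)
      while (is.null(sp) && k < max_alleles) {
        k <- k + 1L
        sp <- spectrum_k(h, k)
      }
      if (is.null(sp) || k > max_alleles)
        stop("target he = ", h, " infeasible with at most ", max_alleles,
             " alleles", call. = FALSE)
    }
    if (abs((1 - sum(sp^2)) - h) > 1e-6)
      stop("internal error: spectrum misses target ", h, call. = FALSE)
    names(sp) <- paste0("a", seq_along(sp))
    out[[i]] <- sp
  }
  names(out) <- nm
  allele_freq_table(out)
}

#' Founder allele frequencies emulating the urban study population
#'
#' Spectra matched per locus to the printed expected heterozygosities of the
#' 12 polymorphic microsatellite loci ([sceaux_locus_he()]); mean gene
#' diversity 0.4745.
#'
#' @param ... Passed to [freqs_from_target_he()] (e.g. `n_alleles`).
#' @return An [allele_freq_table()] of 12 loci.
#' @export
sceaux_founder_freqs <- function(...) {
  freqs_from_target_he(sceaux_locus_he(), ...)
}

#' Generate a Hardy-Weinberg genotype table
#'
#' Draws `n` individuals with independent loci, two allele copies per locus
#' from the given frequencies (Hardy-Weinberg proportions), then masks whole
#' genotypes at random with probability `missing_rate` per individual-locus
#' (emulating incomplete amplification of non-invasive samples).
#'
#' @param freqs An [allele_freq_table()].
#' @param n Number of individuals.
#' @param missing_rate Per-entry missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [genotypes()] table (empty data frame when `n = 0`).
#' @export
synth_genotypes <- function(freqs, n, missing_rate = 0, seed = 1L) {
  check_freq_table(freqs)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  loci <- names(freqs)
  if (n == 0L)
    return(structure(data.frame(individual = character(0),
                                locus = character(0),
                                allele1 = character(0),
                                allele2 = character(0)),
                     class = c("genotypes", "data.frame")))
  rows <- lapply(loci, function(l) {
    p <- freqs[[l]]
    al <- names(p)
    a1 <- al[sample.int(length(p), n, replace = TRUE, prob = p)]
    a2 <- al[sample.int(length(p), n, replace = TRUE, prob = p)]
    miss <- stats::runif(n) < missing_rate
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
    data.frame(individual = sprintf("ind%03d", seq_len(n)), locus = l,
               allele1 = a1, allele2 = a2)
  })
  genotypes(do.call(rbind, rows))
}

#' Preset haplotype structure emulating the park's mitochondrial sample
#'
#' Three D-loop haplotypes on a 486 bp fragment at frequencies
#' (0.54, 0.31, 0.15): haplotype diversity `(1 - sum p^2) n/(n-1)` close to
#' 0.60 at n = 65. Haplotype 2 differs from haplotype 1 at 8 sites and
#' haplotype 3 carries those 8 plus 2 more, giving an expected nucleotide
#' diversity near 0.0093.
#'
#' @return List with `hap_freqs`, `length`, `divergence_positions` (list of
#'   mutated positions per haplotype, relative to haplotype 1).
#' @export
sceaux_mtdna_preset <- function() {
  base_pos <- seq(40, 40 + 7 * 55, by = 55) # 8 spread-out sites
  list(hap_freqs = c(h1 = 0.54, h2 = 0.31, h3 = 0.15),
       length = 486L,
       divergence_positions = list(h1 = integer(0),
                                   h2 = base_pos,
                                   h3 = c(base_pos, c(470L, 480L))))
}

mutate_base <- function(b) {
  bases <- c("A", "C", "G", "T")
  vapply(b, function(z) sample(setdiff(bases, z), 1L), "")
}

#' Generate an aligned haplotype-structured sequence sample
#'
#' Builds a random reference sequence, derives each haplotype by
#' substituting the bases at its divergence positions, and samples `n`
#' sequences at the given haplotype frequencies.
#'
#' @param hap_freqs Named haplotype frequencies (sum to 1).
#' @param n Number of sequences.
#' @param length Alignment length (bp).
#' @param divergence_positions List (one element per haplotype) of positions
#'   mutated relative to the reference; shared positions receive the same
#'   substitution, so pairwise differences are set differences.
#' @param seed Integer seed.
#' @return Character matrix (sequences x sites) with haplotype-labelled row
#'   names; attribute `haplotype` holds each row's haplotype.
#' @export
synth_sequences <- function(hap_freqs, n, length = 486L,
                            divergence_positions = NULL, seed = 1L) {
  if (abs(sum(hap_freqs) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  H <- base::length(hap_freqs)
  if (is.null(divergence_positions))
    divergence_positions <- c(list(integer(0)),
                              lapply(seq_len(H - 1L), function(i)
                                seq_len(3L) + 3L * (i - 1L)))
  if (any(unlist(divergence_positions) > length))
    stop("divergence positions exceed alignment length", call. = FALSE)
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  all_pos <- sort(unique(unlist(divergence_positions)))
  subs <- mutate_base(ref[all_pos]) # one shared substitution per site
  names(subs) <- all_pos
  haps <- lapply(divergence_positions, function(pos) {
    h <- ref
    if (base::length(pos)) h[pos] <- subs[as.character(pos)]
    h
  })
  idx <- sample.int(H, n, replace = TRUE, prob = hap_freqs)
  m <- do.call(rbind, haps[idx])
  hap_names <- if (!is.null(names(hap_freqs))) names(hap_freqs)
               else paste0("h", seq_len(H))
  rownames(m) <- sprintf("%s_seq%03d", hap_names[idx], seq_len(n))
  structure(m, haplotype = hap_names[idx])
}

#' Generate line-transect sighting records
#'
#' Places a Poisson number of animals in each surveyed strip (density times
#' strip area `2 w L`), assigns uniform perpendicular distances, and thins
#' by the detection function `g(x)`.
#'
#' @param density_ha Named vector of true densities (individuals/ha) per
#'   stratum.
#' @param transects Data frame `transect_id`, `stratum`, `length_m`.
#' @param w Strip half-width surveyed (meters).
#' @param detect List `key`, `sigma`, and `b` for the hazard-rate key;
#'   `NULL` for perfect detection.
#' @param seed Integer seed.
#' @return Data frame `transect_id`, `stratum`, `distance_m` (class
#'   `sightings`).
#' @export
synth_sightings <- function(density_ha, transects, w = 50,
                            detect = list(key = "hazard", sigma = 12,
                                          b = 3),
                            seed = 1L) {
  if (any(density_ha < 0)) stop("densities must be non-negative",
                                call. = FALSE)
  unknown <- setdiff(unique(transects$stratum), names(density_ha))
  if (length(unknown))
    stop("no density given for stratum: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(transects)), function(i) {
    tr <- transects[i, ]
    strip_ha <- 2 * w * tr$length_m / 1e4
    n_animals <- stats::rpois(1, density_ha[[tr$stratum]] * strip_ha)
    if (n_animals == 0L) return(NULL)
    x <- stats::runif(n_animals, 0, w)
    if (!is.null(detect)) {
      g <- key_fn(detect$key, x, detect$sigma, detect$b)
      x <- x[stats::runif(n_animals) < g]
    }
    if (!length(x)) return(NULL)
    data.frame(transect_id = tr$transect_id, stratum = tr$stratum,
               distance_m = x)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(transect_id = character(0), stratum = character(0),
                         distance_m = numeric(0))
  rownames(out) <- NULL
  structure(out, class = c("sightings", "data.frame"))
}
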