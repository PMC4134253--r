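# Readers and writers for the package's plain-text dialects, plus run
# manifests for reproducibility.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path,
                               call. = FALSE)
  if (file.size(path) == 0L) stop(what, " file is empty: ", path,
                                  call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(what, " file has no data rows: ", path,
                           call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read a genotype CSV
#'
#' Dialect: `individual,locus,allele1,allele2`, one row per individual x
#' locus; an empty allele field means missing (both must be empty).
#' Malformed rows are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return A [genotypes()] table.
#' @export
read_genotypes <- function(path) {
  df <- read_csv_checked(path, c("individual", "locus", "allele1",
                                 "allele2"), "genotype")
  df$allele1 <- as.character(df$allele1)
  df$allele2 <- as.character(df$allele2)
  df$allele1[df$allele1 == ""] <- NA_character_
  df$allele2[df$allele2 == ""] <- NA_character_
  half <- xor(is.na(df$allele1), is.na(df$allele2))
  if (any(half))
    stop("malformed genotype row(s) (one allele missing) at data row(s): ",
         paste(utils::head(which(half), 5L), collapse = ", "),
         " of ", path, call. = FALSE)
  genotypes(df)
}

#' Write a genotype CSV
#'
#' @param g A [genotypes()] table.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_genotypes <- function(g, path) {
  g <- genotypes(g)
  out <- as.data.frame(g)
  out$allele1[is.na(out$allele1)] <- ""
  out$allele2[is.na(out$allele2)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file.
#' @return Character matrix (sequences x sites); errors on ragged
#'   alignments or empty files.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path,
                               call. = FALSE)
  seqs <- ape::read.FASTA(path)
  if (!length(seqs)) stop("FASTA file is empty: ", path, call. = FALSE)
  as_seq_matrix(seqs)
}

#' Write sequences to FASTA
#'
#' @param m Character matrix (sequences x sites) with row names.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_fasta_alignment <- function(m, path) {
  lines <- character(0)
  for (i in seq_len(nrow(m))) {
    nm <- rownames(m)[i]
    if (is.null(nm)) nm <- paste0("seq", i)
    lines <- c(lines, paste0(">", nm), paste0(m[i, ], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sightings CSV
#'
#' Dialect: `transect_id,stratum,distance_m`. Non-numeric or negative
#' distances are reported with their row numbers; unknown stratum labels
#' (when `strata` is given) are an error.
#'
#' @param path CSV file path.
#' @param strata Optional vector of allowed stratum labels.
#' @return Data frame of class `sightings`.
#' @export
read_sightings <- function(path, strata = NULL) {
  df <- read_csv_checked(path, c("transect_id", "stratum", "distance_m"),
                         "sightings")
  d <- suppressWarnings(as.numeric(df$distance_m))
  bad <- which(!is.finite(d) | d < 0)
  if (length(bad))
    stop("malformed sighting distance at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), " of ", path,
         call. = FALSE)
  df$distance_m <- d
  if (!is.null(strata)) {
    unknown <- setdiff(unique(df$stratum), strata)
    if (length(unknown))
      stop("unknown stratum label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  structure(df, class = c("sightings", "data.frame"))
}

#' Read a transect effort CSV
#'
#' Dialect: `transect_id,length_m,stratum`.
#'
#' @param path CSV file path.
#' @param strata Optional vector of allowed stratum labels.
#' @return Data frame.
#' @export
read_effort <- function(path, strata = NULL) {
  df <- read_csv_checked(path, c("transect_id", "length_m", "stratum"),
                         "effort")
  l <- suppressWarnings(as.numeric(df$length_m))
  bad <- which(!is.finite(l) | l <= 0)
  if (length(bad))
    stop("malformed transect length at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), " of ", path,
         call. = FALSE)
  df$length_m <- l
  if (!is.null(strata)) {
    unknown <- setdiff(unique(df$stratum), strata)
    if (length(unknown))
      stop("unknown stratum label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  df
}

#' Run manifest for reproducible outputs
#'
#' Captures everything needed to regenerate an output bit for bit: the
#' command label, the fully resolved configuration, the seed, package and R
#' versions, a timestamp and the MD5 digests of any input files.
#'
#' @param command Short label of the producing operation.
#' @param config Named list of resolved parameters.
#' @param seed Integer seed used (or `NULL` for deterministic outputs).
#' @param inputs Character vector of input file paths to digest.
#' @return Named list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = list(), seed = NULL,
                         inputs = character(0)) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    as.list(d)
  } else list()
  structure(list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("parkviable")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input_digests = digests), class = "run_manifest")
}

summary_as_list <- function(x) {
  if (inherits(x, "pva_summary")) {
    out <- unclass(x)
    out$n_trajectory_mean <- as.numeric(out$n_trajectory_mean)
    return(out)
  }
  if (inherits(x, c("stratum_density", "abundance_estimate",
                    "run_manifest")))
    return(unclass(x))
  x
}

#' Write a result object with a reproducibility manifest
#'
#' Data frames are written as CSV or JSON; summary objects as JSON. A
#' `<path>.manifest.json` sidecar records the [run_manifest()].
#'
#' @param obj A data frame, `pva_summary`, `stratum_density` or
#'   `abundance_estimate`.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (data frames only; other objects are
#'   always JSON).
#' @param manifest A [run_manifest()], or `NULL` to skip the sidecar.
#' @return `path` invisibly.
#' @export
write_results <- function(obj, path, format = c("csv", "json"),
                          manifest = NULL) {
  format <- match.arg(format)
  if (is.data.frame(obj) && format == "csv") {
    utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(summary_as_list(obj), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "columns",
                         na = "null")
  }
  if (!is.null(manifest))
    jsonlite::write_json(unclass(manifest), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a JSON results file
#'
#' @param path JSON file written by [write_results()].
#' @return A list (data frames restored for column-oriented payloads).
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
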