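## Plain-text interchange: CSV readers/writers for pedigrees, maps,
## genotypes, phenotypes, temperatures, traits and BLUPs; JSON for truth
## sets and manifests. All dates are ISO-8601.

#' @rdname pedqtl-io
#' @param pedigree,path,map,genotypes,observations,series,traits,blups objects
#'   to write / file paths.
#' @name pedqtl-io
#' @title Read and write the package's tabular formats
#' @description Writers emit the documented CSV headers; readers validate
#'   and rebuild the package's classed objects.
NULL

#' @rdname pedqtl-io
#' @export
write_pedigree_csv <- function(pedigree, path) {
  write.csv(as.data.frame(pedigree)[, c("id", "sire", "dam", "genotyped",
                                        "family")],
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pedqtl-io
#' @export
read_pedigree_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  stopifnot(all(c("id", "sire", "dam") %in% names(df)))
  df$genotyped <- if ("genotyped" %in% names(df))
    as.logical(df$genotyped) else TRUE
  if (!"family" %in% names(df)) df$family <- NA_character_
  structure(df[, c("id", "sire", "dam", "genotyped", "family")],
            class = c("pedigree", "data.frame"))
}

#' @rdname pedqtl-io
#' @export
write_map_csv <- function(map, path) {
  write.csv(data.frame(marker = map$marker, lg = map$lg, cM = map$pos),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname pedqtl-io
#' @export
read_map_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  genetic_map(df$marker, df$lg, df$cM)
}

#' @rdname pedqtl-io
#' @export
write_genotypes_csv <- function(genotypes, path) {
  ph <- matrix(paste(genotypes$hap_m, genotypes$hap_p, sep = "|"),
               nrow(genotypes$hap_m),
               dimnames = dimnames(genotypes$hap_m))
  df <- data.frame(id = rownames(ph), ph, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pedqtl-io
#' @export
write_phenotype_csv <- function(observations, path) {
  obs <- observations
  obs$budbreak_date <- format(as.Date(obs$budbreak_date))
  obs$flowering_date <- format(as.Date(obs$flowering_date))
  write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pedqtl-io
#' @export
read_phenotype_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$budbreak_date <- as.Date(df$budbreak_date)
  df$flowering_date <- as.Date(df$flowering_date)
  df
}

#' @rdname pedqtl-io
#' @export
write_temperature_csv <- function(series, path) {
  write.csv(data.frame(site = series$site,
                       timestamp = format(series$timestamp,
                                          "%Y-%m-%dT%H:%M:%SZ"),
                       temp_C = series$temp_C),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname pedqtl-io
#' @export
read_temperature_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  temperature_series(df$site[1L],
                     as.POSIXct(df$timestamp, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%SZ"),
                     df$temp_C)
}

#' @rdname pedqtl-io
#' @export
write_traits_csv <- function(traits, path) {
  write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pedqtl-io
#' @export
write_blups_csv <- function(blups, path) {
  write.csv(blups, path, row.names = FALSE)
  invisible(path)
}

#' Write a QTL truth set as JSON
#'
#' @param truth a [qtl_truth()] table.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(as.data.frame(truth), path, digits = NA)
  invisible(path)
}

#' Write a chain archive as CSV
#'
#' Tabular stored samples: one row per stored QTL entry plus per-sample
#' rows for the intercept, residual variance and QTL count.
#'
#' @param chain a [mcmc_run()] result.
#' @param path output path.
#' @export
write_chain_csv <- function(chain, path) {
  per_sample <- data.frame(sample = seq_len(chain$n_store),
                           count = chain$count, mu = chain$mu,
                           se2 = chain$se2)
  merged <- merge(per_sample, chain$qtls, by = "sample", all.x = TRUE)
  write.csv(merged[order(merged$sample), ], path, row.names = FALSE,
            na = "")
  invisible(path)
}

## small deterministic content checksum (vectorized weighted byte sum)
content_hash <- function(x) {
  bytes <- if (is.character(x) && length(x) == 1L && file.exists(x))
    readBin(x, "raw", file.info(x)$size) else serialize(x, NULL,
                                                        version = 2)
  b <- as.double(as.integer(bytes))
  w <- (seq_along(b) - 1) %% 9973 + 1
  sprintf("%010.0f-%d", (sum(b * w) + sum(b)) %% 2^31, length(b))
}
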