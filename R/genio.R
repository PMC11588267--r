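# Data containers and plain-text I/O: genotype matrices, locality tables,
# call tables, per-locality allele-frequency profiles, transect distances.

MISSING_ALLELE <- -9L

#' Diploid genotype dataset
#'
#' Container for an individuals-by-loci matrix of alternate-allele counts
#' (0, 1, 2 or `NA` for missing), together with individual ids, locality ids
#' and optional reference-panel membership.
#'
#' @param geno Integer matrix, individuals in rows, loci in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param individuals Character vector of unique individual ids (row names).
#' @param localities Character vector mapping each individual to a locality.
#' @param loci Character vector of unique locus ids (column names). Ids of
#'   the form `"<radtag>_<snp>"` group SNPs into RAD loci for per-locus
#'   thinning.
#' @param panel Optional character vector per individual with values in
#'   `"refA"`, `"refB"`, `"transect"`; defaults to `"transect"`.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, individuals, localities, loci,
                             panel = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stop_if(length(individuals) != nrow(geno),
          "number of individuals does not match genotype rows")
  stop_if(length(loci) != ncol(geno),
          "number of loci does not match genotype columns")
  stop_if(length(localities) != length(individuals),
          "localities must map one locality per individual")
  stop_if(anyDuplicated(individuals) > 0, "duplicated individual ids")
  stop_if(anyDuplicated(loci) > 0, "duplicated locus ids")
  bad <- !is.na(geno) & !(geno %in% 0:2)
  stop_if(any(bad), "genotype entries must be 0, 1, 2 or NA")
  if (is.null(panel)) panel <- rep("transect", length(individuals))
  stop_if(!all(panel %in% c("refA", "refB", "transect")),
          "panel labels must be refA, refB or transect")
  dimnames(geno) <- list(as.character(individuals), as.character(loci))
  structure(
    list(geno = geno,
         individuals = as.character(individuals),
         localities = as.character(localities),
         loci = as.character(loci),
         panel = as.character(panel)),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  tab <- table(x$panel)
  cat("  panels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param ds A [genotype_dataset()].
#' @param loci,individuals Ids to keep (either may be `NULL` to keep all).
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(ds, loci = NULL, individuals = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  li <- if (is.null(loci)) ds$loci else loci
  stop_if(!all(li %in% ds$loci), "unknown locus ids in subset")
  ii <- if (is.null(individuals)) ds$individuals else individuals
  stop_if(!all(ii %in% ds$individuals), "unknown individual ids in subset")
  ridx <- match(ii, ds$individuals)
  genotype_dataset(ds$geno[ridx, match(li, ds$loci), drop = FALSE],
                   ii, ds$localities[ridx], li, ds$panel[ridx])
}

#' Combine two genotype datasets on their shared loci
#'
#' Rows (individuals) are concatenated; loci are intersected in the order of
#' the first dataset.
#'
#' @param a,b [genotype_dataset()] objects with disjoint individual ids.
#' @return A `genotype_dataset`.
#' @export
combine_datasets <- function(a, b) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  shared <- intersect(a$loci, b$loci)
  stop_if(length(shared) == 0, "datasets share no loci")
  stop_if(length(intersect(a$individuals, b$individuals)) > 0,
          "datasets share individual ids")
  aa <- subset_dataset(a, loci = shared)
  bb <- subset_dataset(b, loci = shared)
  genotype_dataset(rbind(aa$geno, bb$geno),
                   c(aa$individuals, bb$individuals),
                   c(aa$localities, bb$localities),
                   shared,
                   c(aa$panel, bb$panel))
}

#' Locality table
#'
#' @param locality Character vector of unique locality ids.
#' @param latitude,longitude Decimal degrees (WGS84 assumed).
#' @param transect_distance_km Optional non-negative distances along the
#'   transect; `NA` entries can be filled by [transect_distance()].
#' @param number Optional integer locality number.
#' @return A `data.frame` with class `locality_table`.
#' @export
locality_table <- function(locality, latitude, longitude,
                           transect_distance_km = NA_real_, number = NA_integer_) {
  stop_if(anyDuplicated(locality) > 0, "duplicated locality ids")
  stop_if(any(abs(latitude) > 90, na.rm = TRUE), "latitude outside [-90, 90]")
  stop_if(any(abs(longitude) > 180, na.rm = TRUE), "longitude outside [-180, 180]")
  stop_if(any(transect_distance_km < 0, na.rm = TRUE),
          "transect distances must be non-negative")
  out <- data.frame(locality = as.character(locality),
                    number = as.integer(number),
                    latitude = as.numeric(latitude),
                    longitude = as.numeric(longitude),
                    transect_distance_km = as.numeric(transect_distance_km),
                    stringsAsFactors = FALSE)
  class(out) <- c("locality_table", "data.frame")
  out
}

EARTH_RADIUS_KM <- 6371

#' Great-circle distance between coordinate pairs
#'
#' Haversine formula on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  d2r <- pi / 180
  dlat <- (lat2 - lat1) * d2r / 2
  dlon <- (lon2 - lon1) * d2r / 2
  a <- sin(dlat)^2 + cos(lat1 * d2r) * cos(lat2 * d2r) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Fill transect distances from an origin locality
#'
#' Distances are straight-line great-circle distances from `origin`, not
#' cumulative path lengths. User-supplied (non-`NA`) distances are kept
#' untouched.
#'
#' @param localities A [locality_table()] with all coordinates present.
#' @param origin Locality id used as the 0 km end of the transect.
#' @return The locality table with `transect_distance_km` filled in.
#' @export
transect_distance <- function(localities, origin) {
  stopifnot(inherits(localities, "data.frame"))
  i <- match(origin, localities$locality)
  stop_if(is.na(i), sprintf("unknown origin locality '%s'", origin))
  stop_if(any(is.na(localities$latitude)) || any(is.na(localities$longitude)),
          "all coordinates must be present to compute distances")
  d <- haversine_km(localities$latitude[i], localities$longitude[i],
                    localities$latitude, localities$longitude)
  keep <- !is.na(localities$transect_distance_km)
  localities$transect_distance_km[!keep] <- d[!keep]
  localities
}

#' Advertisement-call table
#'
#' Per-individual call parameters: dominant frequency DF (Hz), note duration
#' ND (s), rising time RT (s) and pulse rate PR (s^-1), with recording
#' temperature and a species-by-context group label.
#'
#' @param individual,locality Character ids.
#' @param group One of `"allopatric-A"`, `"allopatric-B"`, `"parapatric-A"`,
#'   `"parapatric-B"` per individual.
#' @param temperature_C Air temperature at recording.
#' @param DF_Hz,ND_s,RT_s,PR_per_s The four call parameters.
#' @param SVL_mm Optional snout-vent length.
#' @return A `data.frame` with class `call_table`.
#' @export
call_table <- function(individual, locality, group, temperature_C,
                       DF_Hz, ND_s, RT_s, PR_per_s, SVL_mm = NA_real_) {
  grp <- c("allopatric-A", "allopatric-B", "parapatric-A", "parapatric-B")
  stop_if(!all(group %in% grp), "invalid group label")
  stop_if(any(DF_Hz <= 0), "DF must be positive")
  stop_if(any(ND_s <= 0), "ND must be positive")
  stop_if(any(RT_s < 0), "RT must be non-negative")
  stop_if(any(PR_per_s <= 0), "PR must be positive")
  stop_if(any(RT_s > ND_s), "rising time cannot exceed note duration")
  out <- data.frame(individual = as.character(individual),
                    locality = as.character(locality),
                    group = factor(group, levels = grp),
                    temperature_C = as.numeric(temperature_C),
                    SVL_mm = as.numeric(SVL_mm),
                    DF_Hz = as.numeric(DF_Hz),
                    ND_s = as.numeric(ND_s),
                    RT_s = as.numeric(RT_s),
                    PR_per_s = as.numeric(PR_per_s),
                    stringsAsFactors = FALSE)
  class(out) <- c("call_table", "data.frame")
  out
}

#' Per-locality allele-frequency profile
#'
#' Long-format table of derived-allele counts per locality per locus, with
#' transect distances — the cline-fitting input.
#'
#' @param locus,locality Character ids.
#' @param distance_km Non-negative transect distance of the locality.
#' @param derived Derived-allele count (may be fractional for effective
#'   counts such as mean-ancestry pseudo-data).
#' @param total Total allele count sampled.
#' @return A `data.frame` with class `frequency_profile`.
#' @export
frequency_profile <- function(locus, locality, distance_km, derived, total) {
  stop_if(any(distance_km < 0), "distances must be non-negative")
  stop_if(any(derived < 0) || any(derived > total),
          "derived counts must lie in [0, total]")
  stop_if(any(total <= 0), "total allele counts must be positive")
  out <- data.frame(locus = as.character(locus),
                    locality = as.character(locality),
                    distance_km = as.numeric(distance_km),
                    derived = as.numeric(derived),
                    total = as.numeric(total),
                    stringsAsFactors = FALSE)
  class(out) <- c("frequency_profile", "data.frame")
  out
}

## ---- CSV I/O -------------------------------------------------------------

#' Write / read the CSV representations
#'
#' All tables round-trip losslessly through headered CSV. Genotype CSV stores
#' individuals in rows with `individual`, `locality`, `panel` columns followed
#' by one column per locus.
#'
#' @param ds,x Object to write.
#' @param path File path.
#' @return `read_*` functions return the corresponding object.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_genotype_csv <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  df <- data.frame(individual = ds$individuals, locality = ds$localities,
                   panel = ds$panel, ds$geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("individual", "locality", "panel")
  stop_if(!all(need %in% names(df)), "malformed genotype CSV header")
  loci <- setdiff(names(df), need)
  stop_if(length(loci) == 0, "genotype CSV contains no locus columns")
  g <- as.matrix(df[, loci, drop = FALSE])
  storage.mode(g) <- "integer"
  genotype_dataset(g, df$individual, df$locality, loci, df$panel)
}

#' @rdname csv_io
#' @export
write_locality_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_locality_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locality", "latitude", "longitude")
  stop_if(!all(need %in% names(df)), "malformed locality CSV header")
  locality_table(df$locality, df$latitude, df$longitude,
                 if ("transect_distance_km" %in% names(df))
                   df$transect_distance_km else NA_real_,
                 if ("number" %in% names(df)) df$number else NA_integer_)
}

#' @rdname csv_io
#' @export
write_call_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_call_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "locality", "group", "temperature_C",
            "DF_Hz", "ND_s", "RT_s", "PR_per_s")
  stop_if(!all(need %in% names(df)), "malformed call CSV header")
  call_table(df$individual, df$locality, df$group, df$temperature_C,
             df$DF_Hz, df$ND_s, df$RT_s, df$PR_per_s,
             if ("SVL_mm" %in% names(df)) df$SVL_mm else NA_real_)
}

#' @rdname csv_io
#' @export
write_frequency_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_frequency_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "locality", "distance_km", "derived", "total")
  stop_if(!all(need %in% names(df)), "malformed frequency CSV header")
  frequency_profile(df$locus, df$locality, df$distance_km, df$derived, df$total)
}

## ---- STRUCTURE-style and minimal VCF genotype text -----------------------

#' Read a genotype matrix
#'
#' @param path Input file.
#' @param format `"csv"` (the package's own table), `"structure_like"`
#'   (two rows per individual, alleles coded 1/2, missing -9, header row of
#'   locus ids) or `"vcf_minimal"` (GT field only; requires the
#'   VariantAnnotation package). Unparseable or multi-allelic records are
#'   dropped with a message reporting the count.
#' @return A [genotype_dataset()].
#' @export
read_genotype_matrix <- function(path,
                                 format = c("csv", "structure_like",
                                            "vcf_minimal")) {
  format <- match.arg(format)
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  switch(format,
         csv = read_genotype_csv(path),
         structure_like = read_genotype_structure(path),
         vcf_minimal = read_genotype_vcf(path))
}

#' @rdname read_genotype_matrix
#' @param ds Dataset to write.
#' @export
write_genotype_structure <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ds$loci, collapse = " "), con)
  # genotype g = copies of allele "2"; alleles per row: g=0 -> 1/1, 1 -> 1/2
  a1 <- ds$geno; a2 <- ds$geno
  a1[] <- ifelse(is.na(ds$geno), MISSING_ALLELE, ifelse(ds$geno == 2, 2L, 1L))
  a2[] <- ifelse(is.na(ds$geno), MISSING_ALLELE, ifelse(ds$geno >= 1, 2L, 1L))
  for (i in seq_along(ds$individuals)) {
    writeLines(paste(c(ds$individuals[i], ds$localities[i], a1[i, ]),
                     collapse = " "), con)
    writeLines(paste(c(ds$individuals[i], ds$localities[i], a2[i, ]),
                     collapse = " "), con)
  }
  invisible(path)
}

read_genotype_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  stop_if(length(lines) < 3, "empty or truncated STRUCTURE-style file")
  loci <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  body <- lines[-1]
  stop_if(length(body) %% 2 != 0,
          "odd number of genotype rows; expected two rows per individual")
  tok <- strsplit(trimws(body), "[ \t]+")
  bad_len <- vapply(tok, length, 1L) != length(loci) + 2L
  stop_if(any(bad_len), "genotype rows do not match the locus header")
  n <- length(body) / 2
  ids <- character(n); locs <- character(n)
  g <- matrix(NA_integer_, n, length(loci),
              dimnames = list(NULL, loci))
  for (i in seq_len(n)) {
    r1 <- tok[[2 * i - 1]]; r2 <- tok[[2 * i]]
    stop_if(r1[1] != r2[1],
            sprintf("row pair mismatch for individual '%s'", r1[1]))
    ids[i] <- r1[1]; locs[i] <- r1[2]
    v1 <- suppressWarnings(as.integer(r1[-(1:2)]))
    v2 <- suppressWarnings(as.integer(r2[-(1:2)]))
    gi <- (v1 == 2L) + (v2 == 2L)
    gi[v1 == MISSING_ALLELE | v2 == MISSING_ALLELE] <- NA_integer_
    bad <- (!v1 %in% c(1L, 2L, MISSING_ALLELE)) |
      (!v2 %in% c(1L, 2L, MISSING_ALLELE)) | is.na(v1) | is.na(v2)
    gi[bad & !is.na(bad)] <- NA_integer_
    attr(gi, "bad") <- which(bad)
    g[i, ] <- gi
  }
  stop_if(anyDuplicated(ids) > 0,
          "individual listed more than twice in STRUCTURE-style file")
  # drop loci whose allele coding could not be parsed anywhere
  parse_ok <- colSums(is.na(g)) < n | vapply(seq_along(loci), function(j) {
    any(vapply(seq_len(n), function(i) {
      v1 <- tok[[2 * i - 1]][j + 2]; v1 %in% c("1", "2", "-9")
    }, TRUE))
  }, TRUE)
  if (any(!parse_ok)) {
    message(sprintf("dropped %d unparseable loci", sum(!parse_ok)))
    g <- g[, parse_ok, drop = FALSE]
    loci <- loci[parse_ok]
  }
  genotype_dataset(g, ids, locs, loci)
}

#' @rdname read_genotype_matrix
#' @export
write_genotype_vcf <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ds$individuals), collapse = "\t")),
             con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_along(ds$loci)) {
    g <- ds$geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c("1", j, ds$loci[j], "A", "T", ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  stop_if(is.null(gt), "VCF has no GT field")
  multi <- lengths(VariantAnnotation::alt(vcf)) > 1L
  if (any(multi)) {
    message(sprintf("dropped %d multi-allelic records", sum(multi)))
    gt <- gt[!multi, , drop = FALSE]
  }
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  g <- matrix(map[gt], nrow(gt), ncol(gt), dimnames = dimnames(gt))
  genotype_dataset(t(g), colnames(gt), rep(NA_character_, ncol(gt)),
                   rownames(gt))
}
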