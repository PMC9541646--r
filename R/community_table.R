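#' Long-format community count table
#'
#' The central data structure: one row per observed count of a species at a
#' sampling event. A sampling event is a (time, location, replicate)
#' combination; `replicate` distinguishes repeated observations of the same
#' location and time (e.g. different sampling dates within a year) and may be
#' constant when there are none. Location metadata (coordinates in decimal
#' degrees and/or a habitat label) can be attached for spatial models and
#' habitat splits.
#'
#' @param species Character or factor species identifiers.
#' @param time Numeric time points (years).
#' @param location Character location identifiers.
#' @param replicate Character replicate identifiers (default `"1"`).
#' @param count Nonnegative integer counts.
#' @param locations Optional data frame of location metadata with a
#'   `location` column and any of `latitude`, `longitude`, `habitat`.
#' @return A data frame of class `community_table` with columns `species`,
#'   `time`, `location`, `replicate`, `count` and a `locations` attribute.
#' @export
community_table <- function(species, time, location = "1", replicate = "1",
                            count, locations = NULL) {
  n <- length(count)
  df <- data.frame(species = as.character(species),
                   time = as.numeric(time),
                   location = as.character(rep_len(location, n)),
                   replicate = as.character(rep_len(replicate, n)),
                   count = count,
                   stringsAsFactors = FALSE)
  validate_community_table(df, locations)
}

validate_community_table <- function(df, locations = NULL) {
  req <- c("species", "time", "location", "replicate", "count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(df$count)) || any(df$count < 0))
    stop("counts must be finite and >= 0")
  if (any(df$count != round(df$count)))
    stop("counts must be integers (count data required)")
  df$count <- as.integer(round(df$count))
  key <- paste(df$species, df$time, df$location, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (species, time, location, replicate) rows")
  if (!is.null(locations)) {
    if (!"location" %in% names(locations))
      stop("locations metadata needs a 'location' column")
    locations$location <- as.character(locations$location)
    if (all(c("latitude", "longitude") %in% names(locations))) {
      if (any(abs(locations$latitude) > 90, na.rm = TRUE) ||
          any(abs(locations$longitude) > 180, na.rm = TRUE))
        stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
    }
  }
  attr(df, "locations") <- locations
  class(df) <- c("community_table", "data.frame")
  df
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf(paste0("Community table: %d rows, %d species, %d time points, ",
                     "%d locations, %d replicates\n"),
              nrow(x), length(unique(x$species)), length(unique(x$time)),
              length(unique(x$location)), length(unique(x$replicate))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Species registry of a community table
#'
#' @param x A `community_table`.
#' @return Sorted character vector of all species in the table.
#' @export
species_registry <- function(x) sort(unique(x$species))

#' Insert explicit zeros for unobserved species
#'
#' For every sampling event recorded in the data — every (time, location,
#' replicate) combination that appears — any registered species without a
#' count at that event gains a row with count 0. No new sampling events are
#' invented; the operation is idempotent and preserves all positive counts.
#'
#' @param x A `community_table`.
#' @param registry Species registry to fill against; defaults to all species
#'   present in `x`.
#' @return A zero-filled `community_table`, sorted by species, time,
#'   location, replicate.
#' @export
zero_fill <- function(x, registry = species_registry(x)) {
  stopifnot(inherits(x, "community_table"))
  events <- unique(x[, c("time", "location", "replicate")])
  full <- merge(data.frame(species = registry, stringsAsFactors = FALSE),
                events, by = NULL)
  out <- merge(full, as.data.frame(x), all.x = TRUE,
               by = c("species", "time", "location", "replicate"))
  out$count[is.na(out$count)] <- 0L
  out <- out[order(out$species, out$time, out$location, out$replicate), ,
             drop = FALSE]
  rownames(out) <- NULL
  validate_community_table(out, attr(x, "locations"))
}

#' Subset a community table by habitat label
#'
#' Keeps only locations whose `habitat` metadata matches `label`. The species
#' registry of the subset is restricted to species actually observed (count
#' > 0) in the retained locations, so subsequent zero-filling treats the
#' subset as its own community.
#'
#' @param x A `community_table` with habitat metadata.
#' @param label Habitat label to keep.
#' @return A `community_table` restricted to the matching locations.
#' @export
split_by_habitat <- function(x, label) {
  loc <- attr(x, "locations")
  if (is.null(loc) || !"habitat" %in% names(loc))
    stop("no habitat metadata attached to this table")
  if (!label %in% loc$habitat)
    stop("unknown habitat label '", label, "'; available: ",
         paste(sort(unique(loc$habitat)), collapse = ", "))
  keep_loc <- loc$location[loc$habitat == label]
  out <- x[x$location %in% keep_loc, , drop = FALSE]
  seen <- unique(out$species[out$count > 0])
  out <- out[out$species %in% seen, , drop = FALSE]
  rownames(out) <- NULL
  validate_community_table(as.data.frame(out),
                           loc[loc$location %in% keep_loc, , drop = FALSE])
}

#' Read and write long-format community CSV files
#'
#' The canonical on-disk format: a CSV with columns `species`, `time`,
#' `location`, `replicate`, `count`. Location metadata, when present, is
#' written to a sidecar `<path>.locations.csv` and read back automatically.
#'
#' @param x A `community_table`.
#' @param path CSV file path.
#' @return `write_community_csv` returns `path` invisibly;
#'   `read_community_csv` returns a `community_table`.
#' @export
write_community_csv <- function(x, path) {
  stopifnot(inherits(x, "community_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  loc <- attr(x, "locations")
  if (!is.null(loc))
    write.csv(loc, paste0(path, ".locations.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_csv
#' @export
read_community_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(species = "character", location = "character",
                                replicate = "character"))
  locpath <- paste0(path, ".locations.csv")
  loc <- if (file.exists(locpath)) read.csv(locpath, stringsAsFactors = FALSE)
  validate_community_table(df, loc)
}

#' Read a BioTIME-style raw CSV into a community table
#'
#' Normalizes the column dialect of BioTIME raw-data exports. The default
#' column map targets the standard BioTIME headers; any mapping can be
#' supplied for other dialects. The location identity is formed from the
#' plot column when present, otherwise from rounded coordinates. When a date
#' column is mapped, it becomes the replicate key, so multiple dates within a
#' year count as repeated observations.
#'
#' @param path CSV file path.
#' @param column_map Named list mapping canonical names (`species`, `year`,
#'   `abundance`, `latitude`, `longitude`, and optionally `plot`, `date`,
#'   `habitat`) to the column names in the file. Either a list in R or a
#'   YAML/JSON file path.
#' @return A `community_table` with location metadata attached.
#' @export
read_biotime <- function(path,
                         column_map = list(species = "GENUS_SPECIES",
                                           year = "YEAR",
                                           abundance = "sum.allrawdata.ABUNDANCE",
                                           latitude = "LATITUDE",
                                           longitude = "LONGITUDE",
                                           plot = "PLOT")) {
  if (is.character(column_map) && length(column_map) == 1L) {
    column_map <- if (grepl("\\.json$", column_map, ignore.case = TRUE))
      jsonlite::read_json(column_map, simplifyVector = TRUE)
    else yaml::read_yaml(column_map)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "year", "abundance")
  for (nm in need) {
    col <- column_map[[nm]]
    if (is.null(col) || !col %in% names(raw))
      stop("required column '", nm, "' (mapped to '",
           if (is.null(col)) "<unmapped>" else col, "') not found")
  }
  get <- function(nm) {
    col <- column_map[[nm]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  abundance <- get("abundance")
  if (any(abundance < 0)) stop("negative abundance found")
  if (any(abundance != round(abundance)))
    stop("non-integer abundance: count data required")
  lat <- get("latitude"); lon <- get("longitude"); plot <- get("plot")
  location <- if (!is.null(plot) && !all(is.na(plot)) &&
                  length(unique(plot)) > 1L) {
    as.character(plot)
  } else if (!is.null(lat) && !is.null(lon)) {
    paste0(round(lat, 4), "_", round(lon, 4))
  } else "1"
  date <- get("date")
  replicate <- if (!is.null(date)) as.character(date) else "1"
  df <- data.frame(species = as.character(get("species")),
                   time = as.numeric(get("year")),
                   location = location,
                   replicate = replicate,
                   count = abundance,
                   stringsAsFactors = FALSE)
  # counts recorded more than once per event (e.g. sub-samples) are summed
  agg <- aggregate(count ~ species + time + location + replicate, df, sum)
  locations <- NULL
  if (!is.null(lat) && !is.null(lon)) {
    locations <- unique(data.frame(location = location,
                                   latitude = lat, longitude = lon,
                                   stringsAsFactors = FALSE))
    habitat <- get("habitat")
    if (!is.null(habitat)) {
      hb <- unique(data.frame(location = location,
                              habitat = as.character(habitat),
                              stringsAsFactors = FALSE))
      locations <- merge(locations, hb, by = "location")
    }
    locations <- locations[!duplicated(locations$location), , drop = FALSE]
  }
  validate_community_table(agg, locations)
}
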