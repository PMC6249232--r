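#' Construct a catalogue of identified dolphins
#'
#' The catalogue is the package's data model for photo-identification
#' campaigns. Each entry links one photograph of one named dolphin to an
#' observation date, GPS position and acquisition campaign; an optional table
#' of sighting records adds depth, group size and the set of dolphins seen
#' per survey date.
#'
#' @param entries data.frame with columns `dolphin_name`, `input_image`,
#'   `cropped_fin`, `observation_date` (coercible to `Date`), `gps_lat`,
#'   `gps_lon`, `codename`, and optionally `side` (`"left"`/`"right"`).
#' @param sightings optional data.frame with columns `date`, `gps_lat`,
#'   `gps_lon`, `depth_m`, `group_size`, `dolphins` (list-column of character
#'   vectors, or `;`-joined strings).
#' @return An object of class `catalogue`.
#' @export
catalogue <- function(entries, sightings = NULL) {
  req <- c("dolphin_name", "input_image", "cropped_fin", "observation_date",
           "gps_lat", "gps_lon", "codename")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) == 0L && length(setdiff(req, names(entries))) > 0L)
    entries <- empty_entries()
  miss <- setdiff(req, names(entries))
  if (length(miss) > 0L)
    stop("catalogue schema error: missing attribute(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"side" %in% names(entries))
    entries$side <- rep(NA_character_, nrow(entries))
  if (nrow(entries) > 0L) {
    if (any(is.na(entries$dolphin_name) | entries$dolphin_name == ""))
      stop("validation error: empty dolphin_name in row ",
           which(is.na(entries$dolphin_name) | entries$dolphin_name == "")[1],
           call. = FALSE)
    dt <- tryCatch(as.Date(entries$observation_date),
                   error = function(e) rep(as.Date(NA), nrow(entries)))
    if (any(is.na(dt)))
      stop("validation error: malformed observation_date in row ",
           which(is.na(dt))[1], call. = FALSE)
    entries$observation_date <- dt
    entries$gps_lat <- as.numeric(entries$gps_lat)
    entries$gps_lon <- as.numeric(entries$gps_lon)
    bad <- is.na(entries$gps_lat) | abs(entries$gps_lat) > 90 |
      is.na(entries$gps_lon) | abs(entries$gps_lon) > 180
    if (any(bad))
      stop("validation error: GPS out of range in row ", which(bad)[1],
           call. = FALSE)
    key <- paste(entries$dolphin_name, entries$cropped_fin, sep = "\r")
    if (anyDuplicated(key))
      stop("validation error: duplicate (dolphin_name, cropped_fin) pair in row ",
           which(duplicated(key))[1], call. = FALSE)
  }
  if (!is.null(sightings)) {
    sightings <- normalize_sightings(sightings)
    missing_dates <- setdiff(as.character(entries$observation_date),
                             as.character(sightings$date))
    if (length(missing_dates) > 0L)
      stop("validation error: entry date(s) absent from sightings: ",
           paste(missing_dates, collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries, sightings = sightings),
            class = "catalogue")
}

empty_entries <- function() {
  data.frame(dolphin_name = character(), input_image = character(),
             cropped_fin = character(),
             observation_date = as.Date(character()),
             gps_lat = numeric(), gps_lon = numeric(),
             codename = character(), side = character(),
             stringsAsFactors = FALSE)
}

normalize_sightings <- function(s) {
  s <- as.data.frame(s, stringsAsFactors = FALSE)
  req <- c("date", "gps_lat", "gps_lon", "depth_m", "group_size", "dolphins")
  miss <- setdiff(req, names(s))
  if (length(miss) > 0L)
    stop("sightings schema error: missing attribute(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  s$date <- as.Date(s$date)
  if (any(is.na(s$date)))
    stop("validation error: malformed sighting date", call. = FALSE)
  if (anyDuplicated(s$date))
    stop("validation error: duplicate sighting date", call. = FALSE)
  if (!is.list(s$dolphins))
    s$dolphins <- lapply(strsplit(as.character(s$dolphins), ";", fixed = TRUE),
                         function(x) x[nzchar(x)])
  s$depth_m <- as.numeric(s$depth_m)
  s$group_size <- as.integer(s$group_size)
  if (any(is.na(s$depth_m) | s$depth_m <= 0))
    stop("validation error: depth_m must be positive", call. = FALSE)
  nd <- vapply(s$dolphins, length, integer(1))
  if (any(is.na(s$group_size) | s$group_size < nd))
    stop("validation error: group_size smaller than number of identified dolphins",
         call. = FALSE)
  s
}

#' @export
print.catalogue <- function(x, ...) {
  cat(sprintf("<catalogue: %d entries, %d dolphins, %d dates%s>\n",
              nrow(x$entries), length(unique(x$entries$dolphin_name)),
              length(unique(x$entries$observation_date)),
              if (is.null(x$sightings)) ""
              else sprintf(", %d sightings", nrow(x$sightings))))
  invisible(x)
}

#' Load a catalogue from a JSON or CSV file
#'
#' JSON catalogues are a list of flat objects; CSV catalogues use a header
#' with the same keys (`dolphin_name`, `input_image`, `cropped_fin`,
#' `observation_date`, `gps_lat`, `gps_lon`, `codename`, optional `side`).
#' A sightings companion file, when given, uses keys `date`, `gps_lat`,
#' `gps_lon`, `depth_m`, `group_size`, `dolphins` (`;`-joined in CSV).
#'
#' @param path catalogue file.
#' @param format `"json"` or `"csv"`; default inferred from the extension.
#' @param sightings_path optional sightings file in the same format.
#' @return A [catalogue].
#' @export
load_catalogue <- function(path, format = c("auto", "json", "csv"),
                           sightings_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  read_one <- function(p) {
    if (format == "json") {
      x <- jsonlite::fromJSON(p, simplifyDataFrame = TRUE)
      if (length(x) == 0L) x <- data.frame()
      x
    } else {
      utils::read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
    }
  }
  entries <- read_one(path)
  sightings <- if (!is.null(sightings_path)) read_one(sightings_path) else NULL
  catalogue(entries, sightings)
}

#' Save a catalogue to a JSON or CSV file
#'
#' Dates are serialised as ISO 8601 (`YYYY-MM-DD`) and GPS as signed decimal
#' degrees; a saved catalogue loads back field-for-field identical.
#'
#' @param cat a [catalogue].
#' @param path output file.
#' @param format `"json"` or `"csv"`; default inferred from the extension.
#' @param sightings_path optional output file for the sightings table.
#' @return Invisibly, `path`.
#' @export
save_catalogue <- function(cat, path, format = c("auto", "json", "csv"),
                           sightings_path = NULL) {
  stopifnot(inherits(cat, "catalogue"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  e <- cat$entries
  e$observation_date <- format(e$observation_date, "%Y-%m-%d")
  write_one <- function(df, p) {
    if (format == "json") {
      jsonlite::write_json(df, p, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    } else {
      utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    }
  }
  write_one(e, path)
  if (!is.null(cat$sightings) && !is.null(sightings_path)) {
    s <- cat$sightings
    s$date <- format(s$date, "%Y-%m-%d")
    s$dolphins <- vapply(s$dolphins, paste, character(1), collapse = ";")
    write_one(s, sightings_path)
  }
  invisible(path)
}

#' Enroll fin models from a catalogue
#'
#' Runs every catalogued cropped-fin image through segmentation, sharpness
#' scoring, keypoint detection and the admission filter, then enrolls, for
#' each (dolphin, side) pair with at least one passing image, the passing
#' image with the highest sharpness (ties broken by lexicographically
#' smallest image path). The total model count is therefore
#' `m = sum over dolphins of the number of photographed sides` that pass the
#' gate. Dolphins with no passing image are reported, not silently dropped.
#'
#' @param cat a [catalogue] whose `cropped_fin` paths exist on disk (relative
#'   paths are resolved against `base_dir`).
#' @param side_labels optional named character vector mapping `cropped_fin`
#'   paths to `"left"`/`"right"`; defaults to the catalogue's `side` column,
#'   then to `"left"`.
#' @param quality a [quality_config()].
#' @param backend a [detector_backend()].
#' @param seg_config a [segmentation_config()].
#' @param base_dir directory against which relative image paths are resolved.
#' @return List with `models` (list of `fin_model`) and `unenrollable`
#'   (data.frame of dolphin/side/path/reason for images or dolphins that
#'   could not be enrolled).
#' @export
build_fin_models <- function(cat, side_labels = NULL,
                             quality = quality_config(),
                             backend = detector_backend(),
                             seg_config = segmentation_config(),
                             base_dir = ".") {
  stopifnot(inherits(cat, "catalogue"))
  e <- cat$entries
  if (nrow(e) == 0L) return(list(models = list(), unenrollable = data.frame()))
  side <- e$side
  if (!is.null(side_labels)) side <- unname(side_labels[e$cropped_fin])
  side[is.na(side) | !side %in% c("left", "right")] <- "left"

  cand <- data.frame(dolphin = e$dolphin_name, side = side,
                     path = e$cropped_fin, sharp = NA_real_,
                     pass = FALSE, reason = "", stringsAsFactors = FALSE)
  feats <- vector("list", nrow(cand))
  imgs <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand$path[i]
    full <- if (file.exists(p)) p else file.path(base_dir, p)
    res <- tryCatch({
      img <- read_fin_image(full)
      msk <- extract_fin_mask(img, seg_config)
      fs <- detect_features(img, msk, backend)
      sh <- sharpness(img, msk, scope = quality$sharpness_scope)
      gate <- passes_filter(img, msk, nrow(fs$keypoints), quality)
      list(img = img, fs = fs, sharp = sh, gate = gate)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      cand$reason[i] <- conditionMessage(res)
    } else {
      cand$sharp[i] <- res$sharp
      cand$pass[i] <- res$gate$pass
      cand$reason[i] <- paste(res$gate$reasons, collapse = ";")
      feats[[i]] <- res$fs
      imgs[[i]] <- res$img
    }
  }

  models <- list()
  passing <- which(cand$pass)
  groups <- split(passing, paste(cand$dolphin[passing], cand$side[passing],
                                 sep = "\r"))
  for (g in groups) {
    ord <- g[order(-cand$sharp[g], cand$path[g])]
    i <- ord[1]
    models[[length(models) + 1L]] <-
      fin_model(cand$dolphin[i], cand$side[i], imgs[[i]], feats[[i]],
                sharpness = cand$sharp[i])
  }
  # stable order: by dolphin then side
  if (length(models) > 0L) {
    ord <- order(vapply(models, `[[`, "", "dolphin_name"),
                 vapply(models, `[[`, "", "side"))
    models <- models[ord]
  }
  enrolled <- unique(cand$dolphin[cand$pass])
  unenrollable <- cand[!cand$dolphin %in% enrolled, , drop = FALSE]
  list(models = models, unenrollable = unenrollable)
}
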