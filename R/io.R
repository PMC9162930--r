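# Reading microscope line-profile exports.
#
# LAS X and comparable microscope software export line-profile "histograms"
# as delimited text whose encoding (often UTF-16), delimiter (comma,
# semicolon or tab) and decimal mark (point or comma) depend on software
# version and locale. The reader sniffs all three from content so exports
# can be consumed without manual transcoding.

#' Read line-profile CSV exports into a profile set
#'
#' Reads a delimited text export of per-ROI fluorescence line profiles and
#' returns a [profile_set()]. Two layouts are supported:
#' * **wide** (the usual export): first numeric column = z position in
#'   micrometres, every further numeric column = one ROI's intensity;
#'   column order defines `roi_id` 1..n left to right.
#' * **long**: columns named (case-insensitively) `roi`, `z`, `intensity`
#'   in any order, one row per (ROI, z) pair.
#'
#' Encoding (UTF-8, UTF-8 with BOM, UTF-16 LE/BE, Latin-1), delimiter
#' (comma, semicolon, tab) and decimal mark (point or comma) are detected
#' from the file content; identical numeric content yields an identical
#' profile set in every dialect. No data row is ever silently dropped:
#' ragged or non-numeric rows raise an error naming the file.
#'
#' @param path Path to the export file.
#' @param layout `"auto"` (default; decided by header inspection), `"wide"`
#'   or `"long"`.
#' @param image_id Image identifier stored in the profiles; defaults to the
#'   file name without extension.
#' @param orientation Profile orientation, see [z_profile()].
#' @return A [profile_set()].
#' @export
read_profiles <- function(path, layout = c("auto", "wide", "long"),
                          image_id = NULL,
                          orientation = c("electrode_low_z",
                                          "electrode_high_z")) {
  layout <- match.arg(layout)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- read_text_auto(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("format error in '", path, "': file is empty", call. = FALSE)
  }
  sep <- sniff_delimiter(lines)
  dec <- sniff_decimal(lines, sep)
  df <- tryCatch(
    utils::read.table(text = lines, sep = sep, dec = dec,
                      header = has_header(lines[1], sep, dec),
                      check.names = FALSE, stringsAsFactors = FALSE,
                      fill = FALSE, blank.lines.skip = TRUE,
                      colClasses = NA),
    error = function(e) {
      stop("format error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  num <- vapply(df, is.numeric, logical(1))
  if (!any(num)) {
    stop("format error in '", path, "': no numeric columns after parsing",
         call. = FALSE)
  }
  if (anyNA(df[num])) {
    bad <- which(rowSums(is.na(df[num])) > 0)[1]
    stop("format error in '", path, "': non-numeric value in data row ",
         bad, call. = FALSE)
  }
  if (layout == "auto") layout <- detect_layout(names(df))
  if (layout == "long") {
    build_long(df, image_id, orientation, path)
  } else {
    build_wide(df[num], image_id, orientation, path)
  }
}

build_wide <- function(df, image_id, orientation, path) {
  if (ncol(df) < 2L) {
    stop("format error in '", path,
         "': wide layout needs a z column plus >= 1 intensity column",
         call. = FALSE)
  }
  z <- df[[1]]
  profiles <- lapply(seq_len(ncol(df) - 1L), function(i) {
    z_profile(z, df[[i + 1L]], roi_id = i, image_id = image_id,
              orientation = orientation)
  })
  profile_set(profiles)
}

build_long <- function(df, image_id, orientation, path) {
  nm <- tolower(names(df))
  ir <- match("roi", nm)
  iz <- match("z", nm)
  ii <- match("intensity", nm)
  if (anyNA(c(ir, iz, ii))) {
    stop("format error in '", path,
         "': long layout needs columns roi, z, intensity", call. = FALSE)
  }
  rois <- sort(unique(df[[ir]]))
  profiles <- lapply(seq_along(rois), function(i) {
    sub <- df[df[[ir]] == rois[i], ]
    sub <- sub[order(sub[[iz]]), ]
    z_profile(sub[[iz]], sub[[ii]], roi_id = i, image_id = image_id,
              orientation = orientation)
  })
  profile_set(profiles)
}

detect_layout <- function(nms) {
  nm <- tolower(nms)
  if (all(c("roi", "z", "intensity") %in% nm)) "long" else "wide"
}

# Decode a text file of unknown encoding to UTF-8 lines.
# BOMs identify UTF-8/UTF-16 exactly; BOM-less UTF-16 is recognized by its
# null bytes; remaining content is UTF-8 if it validates, else Latin-1.
read_text_auto <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  enc <- if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xEF, 0xBB, 0xBF)))) {
    raw <- raw[-(1:3)]
    "UTF-8"
  } else if (length(raw) >= 2 && identical(raw[1:2], as.raw(c(0xFF, 0xFE)))) {
    "UTF-16LE"
  } else if (length(raw) >= 2 && identical(raw[1:2], as.raw(c(0xFE, 0xFF)))) {
    "UTF-16BE"
  } else if (any(raw == as.raw(0))) {
    nul <- which(raw == as.raw(0))
    if (mean(nul %% 2 == 0) > 0.5) "UTF-16LE" else "UTF-16BE"
  } else {
    txt <- rawToChar(raw)
    if (validEnc(txt)) "UTF-8" else "latin1"
  }
  txt <- if (enc %in% c("UTF-16LE", "UTF-16BE")) {
    iconv(list(raw), from = enc, to = "UTF-8")
  } else {
    iconv(rawToChar(raw), from = enc, to = "UTF-8")
  }
  if (is.na(txt)) stop("cannot decode '", path, "' (tried ", enc, ")",
                       call. = FALSE)
  strsplit(txt, "\r\n|\r|\n")[[1]]
}

sniff_delimiter <- function(lines) {
  probe <- utils::head(lines, 25L)
  per_line <- function(s) {
    k <- lengths(gregexpr(s, probe, fixed = TRUE))
    k[!vapply(probe, grepl, logical(1), pattern = s, fixed = TRUE)] <- 0L
    k
  }
  seps <- c(";", "\t", ",")
  counts <- lapply(seps, per_line)
  consistent <- vapply(counts, function(k) min(k) == max(k) && min(k) > 0,
                       logical(1))
  if (any(consistent)) {
    # among consistent candidates, prefer the one splitting most fields
    best <- which(consistent)[which.max(vapply(counts[consistent], min, 0L))]
    return(seps[best])
  }
  med <- vapply(counts, function(k) stats::median(k), numeric(1))
  if (all(med == 0)) return(",")  # single column: delimiter irrelevant
  seps[which.max(med)]
}

sniff_decimal <- function(lines, sep) {
  if (sep == ",") return(".")
  body <- utils::head(lines, 50L)
  fields <- unlist(strsplit(body, sep, fixed = TRUE))
  if (any(grepl("^\\s*-?[0-9]+,[0-9]+\\s*$", fields))) "," else "."
}

has_header <- function(first_line, sep, dec) {
  fields <- trimws(strsplit(first_line, sep, fixed = TRUE)[[1]])
  if (dec == ",") fields <- sub(",", ".", fields, fixed = TRUE)
  suppressWarnings(any(is.na(as.numeric(fields[nzchar(fields)]))))
}

#' Write thickness results and summaries to CSV
#'
#' Writes the per-ROI detail table to `path` and companion per-image and
#' per-electrode summary tables next to it (suffixes `_images` and
#' `_electrode`). Output is UTF-8, comma-delimited with period decimals;
#' numeric values are written with full precision so that re-reading the
#' detail file reproduces the thickness values exactly.
#'
#' @param results Tibble from [compute_thickness()]; must be non-empty.
#' @param path Output path of the detail CSV.
#' @param electrode_id Identifier used in the electrode summary row.
#' @return Invisibly, the paths of the three files written.
#' @export
write_results <- function(results, path, electrode_id = "electrode") {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  detail_cols <- c("image_id", "roi_id", "lower_z", "upper_z",
                   "thickness_um", "threshold_left", "threshold_right",
                   "flags")
  detail <- results[intersect(detail_cols, names(results))]
  img <- summarize_images(results)
  ele <- summarize_electrode(img, electrode_id = electrode_id)
  ele$per_image <- NULL

  paths <- c(
    detail = path,
    images = sub("(\\.[[:alnum:]]+)?$", "_images\\1", path),
    electrode = sub("(\\.[[:alnum:]]+)?$", "_electrode\\1", path)
  )
  write_full_precision_csv(detail, paths[["detail"]])
  write_full_precision_csv(img, paths[["images"]])
  write_full_precision_csv(ele, paths[["electrode"]])
  invisible(paths)
}

write_full_precision_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "")
}
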