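# Analysis configuration, per-image symptom reports and their export.

#' Analysis configuration
#'
#' Bundles every user-tunable parameter of the five pipelines with its
#' default.  Thresholds are fractions of the working-scale maximum so a
#' configuration is valid at any bit depth.
#'
#' @param bit_depth Working bits per channel (8 or 10).
#' @param t_leaf Blue-channel leaf threshold (fraction of max).
#' @param t_necro Green-channel necrosis threshold (fraction of max).
#' @param t_spot Blue-channel white-spot threshold (fraction of max).
#' @param se_necrosis Structuring element for the necrosis opening
#'   prefilter.
#' @param se_mosaic Structuring element for the venation hats.
#' @param canny_sigma,canny_lo,canny_hi Canny parameters.
#' @param connectivity 4 or 8.
#' @param masked_centroid Compute the chlorosis centroid over the masked
#'   leaf instead of the whole frame.
#' @param whole_frame_chlorosis Use the whole frame (no leaf mask) for
#'   the chlorosis section means, the literal per-frame definition.
#' @param hat_mode Venation hat combination, `"additive"` or
#'   `"replace"`.
#' @param perimeter_method,perimeter_k Perimeter estimator (see
#'   [measure_area_perimeter()]).
#' @param stretch_hi Upper end of the mosaic working range.
#' @param spot_denoise Pre-open the white-spot mask.
#' @return Object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(bit_depth = 8L, t_leaf = 0.80, t_necro = 0.35,
                            t_spot = 0.80, se_necrosis = se_box(3),
                            se_mosaic = se_disk(4), canny_sigma = 1.4,
                            canny_lo = 0.1, canny_hi = 0.25,
                            connectivity = 8L, masked_centroid = FALSE,
                            whole_frame_chlorosis = FALSE,
                            hat_mode = "additive",
                            perimeter_method = "polygon", perimeter_k = 5L,
                            stretch_hi = 1023, spot_denoise = FALSE) {
  cfg <- list(bit_depth = as.integer(bit_depth), t_leaf = t_leaf,
              t_necro = t_necro, t_spot = t_spot,
              se_necrosis = se_necrosis, se_mosaic = se_mosaic,
              canny_sigma = canny_sigma, canny_lo = canny_lo,
              canny_hi = canny_hi, connectivity = as.integer(connectivity),
              masked_centroid = masked_centroid,
              whole_frame_chlorosis = whole_frame_chlorosis,
              hat_mode = hat_mode, perimeter_method = perimeter_method,
              perimeter_k = as.integer(perimeter_k),
              stretch_hi = stretch_hi, spot_denoise = spot_denoise)
  structure(cfg, class = "analysis_config")
}

# order-independent 32-bit FNV-1a hash of the deparsed configuration
config_hash <- function(cfg) {
  s <- paste(vapply(sort(names(cfg)), function(nm) {
    paste0(nm, "=", paste(deparse(cfg[[nm]]), collapse = ""))
  }, character(1)), collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # (h * m) mod 2^32 in exact double arithmetic, via 16-bit split
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Analyze one image for selected symptoms
#'
#' Runs the requested pipelines on an image and collects their results
#' in a `symptom_report` that also records the configuration hash and
#' any warnings, so a run is exactly reproducible from its report.
#' The mosaic pipeline needs a back-lit photograph; unless `backlit =
#' TRUE` it is skipped with a warning.
#'
#' @param img An [rgb_image()] or a file path.
#' @param symptoms Character vector among `"chlorosis"`, `"necrosis"`,
#'   `"deformation"`, `"white_spots"`, `"mosaic"`, or `"all"`.
#' @param config An [analysis_config()].
#' @param backlit Assert that the image was taken under back-light.
#' @param path Input path recorded in the report.
#' @return Object of class `symptom_report`.
#' @export
analyze_image <- function(img, symptoms = "all", config = analysis_config(),
                          backlit = FALSE, path = NA_character_) {
  if (is.character(img)) {
    path <- img
    img <- read_leaf_image(img, bit_depth = config$bit_depth)
  }
  stopifnot(inherits(img, "rgb_image"))
  all_symptoms <- c("chlorosis", "necrosis", "deformation", "white_spots",
                    "mosaic")
  if (identical(symptoms, "all")) symptoms <- all_symptoms
  bad <- setdiff(symptoms, all_symptoms)
  if (length(bad)) stop("unknown symptom(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  warnings <- character(0)
  out <- list()
  wrap <- function(code) {
    withCallingHandlers(code, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  for (s in symptoms) {
    if (s == "mosaic" && !backlit) {
      warnings <- c(warnings,
                    "mosaic requested on a non-backlit image: skipped")
      next
    }
    out[[s]] <- wrap(switch(s,
      chlorosis = {
        mask <- if (config$whole_frame_chlorosis) NULL else
          segment_leaf(img, config$t_leaf, config$connectivity)
        quantify_chlorosis(img, leaf_mask = mask,
                           masked_centroid = config$masked_centroid)
      },
      necrosis = quantify_necrosis(img, config$t_necro, config$t_leaf,
                                   config$se_necrosis),
      deformation = quantify_deformation(img, config$t_leaf,
                                         config$perimeter_method,
                                         config$perimeter_k),
      white_spots = quantify_white_spots(img, config$t_spot,
                                         config$spot_denoise,
                                         config$connectivity),
      mosaic = quantify_mosaic(img, config$se_mosaic, config$canny_sigma,
                               config$canny_lo, config$canny_hi,
                               config$t_leaf, config$stretch_hi,
                               config$hat_mode)
    ))
  }
  structure(
    list(path = path, config_hash = config_hash(config), results = out,
         warnings = warnings),
    class = "symptom_report"
  )
}

#' @export
print.symptom_report <- function(x, ...) {
  cat(sprintf("<symptom_report> %s [config %s]\n",
              ifelse(is.na(x$path), "<in-memory image>", x$path),
              x$config_hash))
  for (r in x$results) print(r)
  if (length(x$warnings)) {
    cat("  warnings:\n")
    cat(paste0("   - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Batch analysis of several images
#'
#' Errors in one image (e.g. "no leaf found") are reported in that
#' image's entry and the batch continues.
#'
#' @param paths Character vector of image paths, or a list of
#'   [rgb_image()] objects.
#' @param symptoms,config,backlit As in [analyze_image()].
#' @return List of `symptom_report` objects; the attribute `n_errors`
#'   counts failed images.
#' @export
run_leafquant <- function(paths, symptoms = "all",
                          config = analysis_config(), backlit = FALSE) {
  if (length(paths) == 0L) stop("no input images given", call. = FALSE)
  n_err <- 0L
  reports <- lapply(seq_along(paths), function(i) {
    p <- if (is.list(paths)) paths[[i]] else paths[[i]]
    tryCatch(
      analyze_image(p, symptoms, config, backlit),
      error = function(e) {
        n_err <<- n_err + 1L
        structure(list(path = if (is.character(p)) p else NA_character_,
                       config_hash = config_hash(config),
                       results = list(), error = conditionMessage(e),
                       warnings = character(0)),
                  class = "symptom_report")
      }
    )
  })
  attr(reports, "n_errors") <- n_err
  reports
}

report_row <- function(rep) {
  num <- function(x) if (is.null(x)) NA_real_ else x
  ch <- rep$results$chlorosis
  ne <- rep$results$necrosis
  de <- rep$results$deformation
  ws <- rep$results$white_spots
  mo <- rep$results$mosaic
  data.frame(
    path = rep$path,
    config_hash = rep$config_hash,
    error = if (is.null(rep$error)) NA_character_ else rep$error,
    rn = num(ch$rn), rdiff = num(ch$rdiff),
    r1 = num(ch$region_means[1]), r2 = num(ch$region_means[2]),
    r3 = num(ch$region_means[3]), r4 = num(ch$region_means[4]),
    l1 = num(ch$l_counts[1]), l2 = num(ch$l_counts[2]),
    l3 = num(ch$l_counts[3]), l4 = num(ch$l_counts[4]),
    a_np = num(ne$a_np), a_t = num(ne$a_t), a_n = num(ne$a_n),
    area_px = num(de$area_px), perimeter_px = num(de$perimeter_px),
    deformation_index = num(de$index),
    a_zs = num(ws$a_zs), a_bg = num(ws$a_bg), a_tl = num(ws$a_tl),
    a_ws = num(ws$a_ws), a_pws = num(ws$a_pws),
    a_map = num(mo$a_map), a_tl_mosaic = num(mo$a_tl),
    a_mosaic = num(mo$a_mosaic),
    n_warnings = length(rep$warnings),
    stringsAsFactors = FALSE
  )
}

#' Flatten symptom reports to a data frame
#'
#' One row per image, flat columns for every reported quantity.
#'
#' @param reports A list of `symptom_report`s (from [run_leafquant()]).
#' @return A data frame.
#' @export
reports_to_df <- function(reports) {
  if (inherits(reports, "symptom_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, report_row))
}

strip_heavy <- function(rep) {
  rep$results <- lapply(rep$results, function(r) {
    r[!vapply(r, function(x) is.matrix(x) || inherits(x, "struct_elem"),
              logical(1))]
  })
  rep
}

#' Export symptom reports to JSON or CSV
#'
#' CSV holds the flat per-image table; JSON preserves the nested result
#' structure (image rasters and structuring elements are dropped, the
#' scalar parameters that reproduce them are kept).
#'
#' @param reports List of `symptom_report`s.
#' @param path Output file.
#' @param format `"json"` or `"csv"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
export_reports <- function(reports, path, format = NULL) {
  if (inherits(reports, "symptom_report")) reports <- list(reports)
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  format <- match.arg(format, c("json", "csv"))
  if (format == "csv") {
    utils::write.csv(reports_to_df(reports), path, row.names = FALSE)
  } else {
    jsonlite::write_json(lapply(reports, function(r) unclass(strip_heavy(r))),
                         path, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(path)
}
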