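## End-to-end study orchestration: run the Von Kossa, correlation-length and
## localization stages over condition-labelled image sets and emit the
## comparison tables.

.studyDefaults <- function() {
  list(seed = 1L, calibration = 2.73, threshold = "auto", max_lag = "auto",
       dilation_px = 5L, min_area_px = 50L, alpha = 0.05,
       stages = c("vk", "corrlength"), comparisons = list())
}

.resolveConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- .studyDefaults()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]   # plain override
  if (is.null(cfg$groups) || length(cfg$groups) == 0L)
    stop("config must define at least one group")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

## Materialize one group's images: synthetic preset or files on disk.
.materializeGroup <- function(grp, cfg, groupIndex) {
  out <- list()
  if (!is.null(grp$preset)) {
    nimg <- as.integer(grp$n_images %||% 7L)
    kind <- if (grp$preset %in% c("perinuclear_OPN", "diffuse_OPN"))
      "ifscene" else "puncta"
    for (i in seq_len(nimg)) {
      seed_i <- .deriveSeed(cfg$seed, groupIndex * 1000L + i)
      sp <- presetSpec(grp$preset, seed = seed_i,
                       pixelsPerMicron = cfg$calibration)
      if (kind == "puncta") {
        gen <- genPunctaField(sp)
        img <- gen$image
        img@sourceId <- sprintf("%s-%02d", grp$label, i)
        out[[i]] <- list(kind = "puncta", image = img, seed = seed_i)
      } else {
        gen <- genIFScene(sp, dilationPx = cfg$dilation_px)
        st <- gen$stack
        st@sourceId <- sprintf("%s-%02d", grp$label, i)
        out[[i]] <- list(kind = "ifscene", stack = st, seed = seed_i)
      }
    }
  } else if (!is.null(grp$images)) {
    paths <- Sys.glob(grp$images)
    if (length(paths) == 0L) stop("no images match: ", grp$images)
    for (i in seq_along(paths)) {
      img <- readCalibratedImage(paths[i], cfg$calibration)
      if (is(img, "RGBHistologyImage")) img <- rgbToGray8(img)
      out[[i]] <- list(kind = "puncta", image = img, seed = NA_integer_)
    }
  } else if (!is.null(grp$stacks)) {
    paths <- Sys.glob(grp$stacks)
    if (length(paths) == 0L) stop("no stacks match: ", grp$stacks)
    roles <- unlist(grp$channel_roles %||% c("nuclei", "signal"))
    for (i in seq_along(paths)) {
      st <- readMultichannelStack(paths[i], roles, cfg$calibration,
                                  grp$z_step_um %||% 1)
      out[[i]] <- list(kind = "ifscene", stack = st, seed = NA_integer_)
    }
  } else {
    stop("group '", grp$label, "' defines neither preset, images nor stacks")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured study end to end
#'
#' Materializes every group's images (from synthetic presets or files),
#' applies the configured stages — Von Kossa quantification with one
#' condition-uniform threshold pooled over all grayscale images, correlation
#' length, and/or the localization ratio for z-stack groups — aggregates a
#' per-image table and group summaries, and runs the configured comparisons.
#' Rerunning with the same configuration is bit-identical.
#'
#' @param config a list, or path to a YAML file, with keys:
#'   \describe{
#'     \item{groups}{list of groups, each with \code{label}, optional
#'       \code{condition}/\code{sex}, and one of \code{preset} (+
#'       \code{n_images}), \code{images} (glob) or \code{stacks} (glob).}
#'     \item{stages}{subset of \code{c("vk", "corrlength", "localization")}.}
#'     \item{threshold}{"auto" (pooled Otsu) or a fixed integer.}
#'     \item{max_lag}{"auto" (\code{min(dim)/4}) or an integer.}
#'     \item{calibration, dilation_px, min_area_px, alpha, seed}{scalars.}
#'     \item{comparisons}{list of \code{list(measure=, test=, groups=,
#'       posthoc=, control=)} entries; \code{test} is "welch" or "anova".}
#'   }
#' @return a \linkS4class{StudyReport}
#' @export
runStudy <- function(config) {
  cfg <- .resolveConfig(config)
  groups <- cfg$groups
  materialized <- lapply(seq_along(groups), function(gi)
    .materializeGroup(groups[[gi]], cfg, gi))

  # one condition-uniform threshold pooled over every grayscale image
  thresholdUsed <- NA_integer_
  if ("vk" %in% cfg$stages || "corrlength" %in% cfg$stages) {
    grayImgs <- list()
    for (gi in seq_along(groups))
      for (item in materialized[[gi]])
        if (item$kind == "puncta")
          grayImgs[[length(grayImgs) + 1L]] <- item$image
    if (length(grayImgs) > 0) {
      thresholdUsed <- if (identical(cfg$threshold, "auto"))
        autoThreshold(grayImgs) else as.integer(cfg$threshold)
    }
  }

  rows <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    for (ii in seq_along(materialized[[gi]])) {
      item <- materialized[[gi]][[ii]]
      row <- data.frame(group = grp$label,
                        condition = grp$condition %||% NA_character_,
                        sex = grp$sex %||% NA_character_,
                        replicate = ii,
                        source_id = if (item$kind == "puncta")
                          item$image@sourceId else item$stack@sourceId,
                        seed = item$seed,
                        threshold_used = thresholdUsed,
                        n_foreground_px = NA_integer_,
                        integrated_density = NA_real_,
                        area_fraction = NA_real_,
                        normalized_density = NA_real_,
                        correlation_length_px = NA_real_,
                        correlation_length_um = NA_real_,
                        crossing_lag_px = NA_real_,
                        n_nuclei = NA_integer_,
                        cell_mean = NA_real_, ecm_mean = NA_real_,
                        cell_ecm_ratio = NA_real_,
                        cellular_fraction = NA_real_,
                        stringsAsFactors = FALSE)
      if (item$kind == "puncta") {
        mask <- binarizeDark(item$image, thresholdUsed)
        if ("vk" %in% cfg$stages) {
          vk <- vkMeasure(mask, thresholdUsed = thresholdUsed,
                          sourceId = item$image@sourceId)
          row$n_foreground_px <- vk@nForegroundPx
          row$integrated_density <- vk@integratedDensity
          row$area_fraction <- vk@areaFraction
          row$normalized_density <- vk@normalizedDensity
        }
        if ("corrlength" %in% cfg$stages) {
          maxLag <- if (identical(cfg$max_lag, "auto")) NULL else
            as.integer(cfg$max_lag)
          cl <- maskCorrelationLength(mask, maxLagPx = maxLag)
          row$correlation_length_px <- cl@correlationLengthPx
          row$correlation_length_um <- cl@correlationLengthUm
          row$crossing_lag_px <- cl@integrationUpperLagPx
        }
      } else if ("localization" %in% cfg$stages) {
        loc <- localizeStack(item$stack, dilationPx = cfg$dilation_px,
                             minAreaPx = cfg$min_area_px)
        row$n_nuclei <- loc@nNuclei
        row$cell_mean <- loc@cellMean
        row$ecm_mean <- loc@ecmMean
        row$cell_ecm_ratio <- loc@ratio
        row$cellular_fraction <- loc@cellularFraction
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  perImage <- do.call(rbind, rows)

  measures <- c("integrated_density", "area_fraction", "normalized_density",
                "correlation_length_um", "cell_ecm_ratio")
  summ <- list()
  for (msr in measures) {
    v <- perImage[[msr]]
    if (all(is.na(v))) next
    for (g in unique(perImage$group)) {
      vi <- v[perImage$group == g & !is.na(v)]
      if (length(vi) == 0) next
      summ[[length(summ) + 1L]] <- data.frame(
        group = g, measure = msr, mean = mean(vi),
        sd = stats::sd(vi), n = length(vi))
    }
  }
  summaries <- if (length(summ)) do.call(rbind, summ) else
    data.frame(group = character(0), measure = character(0),
               mean = numeric(0), sd = numeric(0), n = integer(0))

  comparisons <- list()
  for (cmp in cfg$comparisons) {
    msr <- cmp$measure
    glabs <- unlist(cmp$groups %||% unique(perImage$group))
    sel <- perImage$group %in% glabs & !is.na(perImage[[msr]])
    v <- perImage[[msr]][sel]
    g <- perImage$group[sel]
    res <- if (identical(cmp$test %||% "welch", "welch")) {
      if (length(glabs) != 2L) stop("welch comparisons need exactly 2 groups")
      welchT(v[g == glabs[1]], v[g == glabs[2]], labels = glabs,
             alpha = cfg$alpha)
    } else {
      oneWayAnova(v, g, posthoc = cmp$posthoc %||% "none",
                  control = cmp$control, alpha = cfg$alpha,
                  mcSeed = cfg$seed)
    }
    comparisons[[paste(msr, paste(glabs, collapse = "-vs-"), sep = ":")]] <-
      res
  }

  cfg$threshold_used <- thresholdUsed
  new("StudyReport", perImageTable = perImage, groupSummaries = summaries,
      comparisons = comparisons, configEcho = cfg)
}

#' Write a study report to disk
#'
#' Emits \code{per_image.csv}, \code{group_summaries.csv},
#' \code{comparisons.csv}, \code{report.json} (config echo plus summaries)
#' and a plain-text log into \code{dir}. Outputs are deterministic: rerunning
#' the same configuration reproduces the files byte for byte.
#'
#' @param report a \linkS4class{StudyReport}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(is(report, "StudyReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report@perImageTable, file.path(dir, "per_image.csv"),
                   row.names = FALSE)
  utils::write.csv(report@groupSummaries,
                   file.path(dir, "group_summaries.csv"), row.names = FALSE)
  cmp <- lapply(names(report@comparisons), function(nm) {
    x <- report@comparisons[[nm]]
    data.frame(comparison = nm, test = x@testName,
               statistic = paste(sprintf("%s=%.6g", names(x@statistic),
                                         x@statistic), collapse = ";"),
               p_value = paste(sprintf("%.6g", x@pValue), collapse = ";"))
  })
  utils::write.csv(if (length(cmp)) do.call(rbind, cmp) else
    data.frame(comparison = character(0)), file.path(dir, "comparisons.csv"),
    row.names = FALSE)
  jsonlite::write_json(
    list(config = report@configEcho,
         group_summaries = report@groupSummaries),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  writeLines(c(sprintf("images: %d", nrow(report@perImageTable)),
               sprintf("threshold_used: %s",
                       report@configEcho$threshold_used),
               sprintf("comparisons: %d", length(report@comparisons))),
             file.path(dir, "log.txt"))
  invisible(dir)
}
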