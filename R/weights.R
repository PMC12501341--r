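#' Load the declarative index weight tables
#'
#' Reads one YAML weight file per index and validates the transcription:
#' duplicate entries, gaps in level coverage, and overlapping or
#' non-contiguous age bands all fail the load with a message naming the
#' offending cell. Points are also carried as integers scaled by 100 so
#' that score sums are exact and order-independent (all published weights
#' have at most two decimals).
#'
#' @param path directory containing the YAML weight files; defaults to the
#'   tables shipped with the package (transcribed from the source
#'   descriptive table, pesticide exposure and chronic kidney disease
#'   omitted).
#' @param overrides optional data frame with columns `index`, `factor`,
#'   `level`, optional `sex`, and `points`, replacing the points of matching
#'   entries. Supports per-cell correction of typographically ambiguous
#'   cells without editing the shipped files.
#' @return a `weight_table` tibble with columns `index`, `factor`, `level`,
#'   `points`, `points_scaled`, `sex`, `age_min`, `age_max`, `demographic`,
#'   `borrowed`, `source_quote`.
#' @export
load_weight_table <- function(path = NULL, overrides = NULL) {
  path <- path %||% demrisk_file("extdata", "weights")
  files <- list.files(path, pattern = "\\.ya?ml$", full.names = TRUE)
  if (length(files) == 0) stop("no weight files found in ", path)
  tabs <- lapply(files, function(f) {
    y <- yaml::read_yaml(f)
    entries <- dplyr::bind_rows(lapply(y$entries, function(e) {
      tibble(
        index = y$index,
        factor = as.character(e$factor),
        level = if (is.logical(e$level)) {
          if (e$level) "yes" else "no"
        } else {
          as.character(e$level)
        },
        points = as.numeric(e$points),
        sex = if (is.null(e$sex)) NA_character_ else e$sex,
        age_min = if (is.null(e$age_min)) NA_real_ else as.numeric(e$age_min),
        age_max = if (is.null(e$age_max)) NA_real_ else as.numeric(e$age_max),
        demographic = isTRUE(e$demographic),
        borrowed = isTRUE(e$borrowed),
        source_quote = if (is.null(e$source_quote)) NA_character_ else e$source_quote
      )
    }))
    entries
  })
  wt <- dplyr::bind_rows(tabs)

  if (!is.null(overrides)) {
    overrides <- as_tibble(overrides)
    for (i in seq_len(nrow(overrides))) {
      o <- overrides[i, ]
      hit <- wt$index == o$index & wt$factor == o$factor & wt$level == o$level
      if ("sex" %in% names(o) && !is.na(o$sex)) {
        hit <- hit & !is.na(wt$sex) & wt$sex == o$sex
      }
      if (!any(hit)) {
        stop("override matches no weight entry: ", o$index, "/", o$factor, "/", o$level)
      }
      wt$points[hit] <- o$points
    }
  }

  wt$points_scaled <- as.integer(round(wt$points * 100))
  if (any(abs(wt$points_scaled / 100 - wt$points) > 1e-9)) {
    bad <- wt[abs(wt$points_scaled / 100 - wt$points) > 1e-9, ]
    stop("weights must have at most two decimals; offending cell: ",
         bad$index[1], "/", bad$factor[1], "/", bad$level[1])
  }
  validate_weight_table(wt)
  class(wt) <- c("weight_table", class(wt))
  wt
}

validate_weight_table <- function(wt) {
  if (any(wt$factor %in% c("pesticide", "kidney_disease", "chronic_kidney_disease"))) {
    stop("weight table contains an omitted item (pesticide / kidney disease)")
  }
  lev <- factor_levels()

  for (ix in unique(wt$index)) {
    w <- wt[wt$index == ix, ]
    for (f in setdiff(unique(w$factor), "age")) {
      wf <- w[w$factor == f, ]
      if (is.null(lev[[f]])) stop("unknown factor in ", ix, ": ", f)
      sexes <- if (all(is.na(wf$sex))) list(NA_character_) else as.list(unique(wf$sex))
      if (!all(is.na(wf$sex)) && !setequal(unique(wf$sex), c("female", "male"))) {
        stop("sex-conditioned factor ", ix, "/", f, " must cover both sexes")
      }
      for (s in sexes) {
        ws <- if (is.na(s)) wf else wf[wf$sex == s, ]
        if (anyDuplicated(ws$level)) {
          stop("duplicate level coverage: ", ix, "/", f, "/",
               ws$level[duplicated(ws$level)][1])
        }
        if (!setequal(ws$level, lev[[f]])) {
          gap <- setdiff(lev[[f]], ws$level)
          stop("gapped level coverage: ", ix, "/", f,
               if (length(gap)) paste0(" missing level '", gap[1], "'") else "")
        }
      }
    }
    # age bands: per sex (or unconditional), contiguous integer cover of 0..200
    wa <- w[w$factor == "age", ]
    if (nrow(wa) > 0) {
      sexes <- if (all(is.na(wa$sex))) list(NA_character_) else list("female", "male")
      for (s in sexes) {
        ws <- if (is.na(s)) wa else wa[!is.na(wa$sex) & wa$sex == s, ]
        ws <- ws[order(ws$age_min), ]
        if (any(is.na(ws$age_min)) || any(is.na(ws$age_max))) {
          stop("age entry without band bounds in ", ix)
        }
        if (ws$age_min[1] != 0 || ws$age_max[nrow(ws)] < 120) {
          stop("age bands do not span the age range in ", ix)
        }
        if (nrow(ws) > 1 && any(ws$age_min[-1] != ws$age_max[-nrow(ws)] + 1)) {
          i <- which(ws$age_min[-1] != ws$age_max[-nrow(ws)] + 1)[1]
          stop("age bands gapped or overlapping in ", ix, " near band '",
               ws$level[i + 1], "'")
        }
      }
    }
  }
  invisible(wt)
}

# Factors an index covers, optionally dropping the demographic block.
covered_factors <- function(weights, index, include_demographics = TRUE) {
  w <- weights[weights$index == index, ]
  if (!include_demographics) w <- w[!w$demographic, ]
  fac <- unique(w$factor)
  # sex-conditioned entries (age bands, CogDrisk diabetes) need sex to resolve
  if (any(!is.na(w$sex))) fac <- union(fac, "sex")
  setdiff(fac, "age")
}
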