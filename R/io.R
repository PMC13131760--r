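#' Read and write session files
#'
#' Session files are comma-separated UTF-8 text with a header row and one
#' identification trial per line (columns `listener_id`, `session_id`,
#' `block`, `consonant`, `vowel`, `recording`, `snr_db`, `response`, `aided`,
#' `correct`). Lines beginning with `#` are provenance comments and are
#' skipped. On read, labels are normalized (IPA aliases accepted) and every
#' record is validated; malformed lines are reported with their line
#' numbers.
#'
#' @param path file path.
#' @return `read_sessions()` returns a validated trial table.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop_qvcv("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         encoding = "UTF-8")
  req <- c("listener_id", "session_id", "block", "consonant", "vowel",
           "recording", "snr_db", "response", "aided", "correct")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop_qvcv(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  # locate offending data lines for the common failure modes
  line_of <- function(rows) paste(rows + 1L, collapse = ", ")  # + header
  ok_cons <- vapply(raw$consonant, function(x)
    !inherits(try(normalize_consonant(x), silent = TRUE), "try-error"),
    logical(1))
  if (any(!ok_cons)) {
    stop_qvcv(path, ": unknown consonant label at line(s) ",
              line_of(which(!ok_cons)))
  }
  ok_resp <- vapply(raw$response, function(x)
    !inherits(try(normalize_response(x), silent = TRUE), "try-error"),
    logical(1))
  if (any(!ok_resp)) {
    stop_qvcv(path, ": unknown response label at line(s) ",
              line_of(which(!ok_resp)))
  }
  snr <- suppressWarnings(as.numeric(raw$snr_db))
  if (any(!is.finite(snr))) {
    stop_qvcv(path, ": non-finite snr_db at line(s) ",
              line_of(which(!is.finite(snr))))
  }
  raw$snr_db <- snr
  raw$correct <- as.logical(raw$correct)
  validate_trials(raw)
}

#' @rdname read_sessions
#' @param trials trial table to write.
#' @param seed,config optional provenance recorded in `#` comment lines.
#' @return `write_sessions()` invisibly returns `path`.
#' @export
write_sessions <- function(trials, path, seed = NULL, config = NULL) {
  trials <- validate_trials(trials)
  .write_csv_with_provenance(trials, path, seed = seed, config = config)
}

#' Read and write listener metadata files
#'
#' Comma-separated files with columns `listener_id`, `measured_pta_db_hl`
#' and optionally `category`, `test_ear`. The category is checked against
#' (or filled from) the PTA bands.
#'
#' @param path file path.
#' @export
read_listener_meta <- function(path) {
  if (!file.exists(path)) stop_qvcv("file not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                          encoding = "UTF-8")
  req <- c("listener_id", "measured_pta_db_hl")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop_qvcv(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  expected <- assign_category(meta$measured_pta_db_hl)
  if (is.null(meta$category)) {
    meta$category <- expected
  } else if (any(meta$category != expected)) {
    stop_qvcv(path, ": category inconsistent with PTA bands for listener(s) ",
              paste(meta$listener_id[meta$category != expected], collapse = ", "))
  }
  meta
}

#' @rdname read_listener_meta
#' @param meta metadata table to write.
#' @param seed,config optional provenance comments.
#' @export
write_listener_meta <- function(meta, path, seed = NULL, config = NULL) {
  .write_csv_with_provenance(meta, path, seed = seed, config = config)
}

#' Read and write token panels as JSON
#'
#' The panel file is the contract between token selection, simulation and
#' scoring: a JSON object with a version tag and one record per token
#' (`consonant`, `vowel`, `snr_db`, `auc`).
#'
#' @param path file path.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_qvcv("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$entries)) stop_qvcv(path, ": not a panel file (no entries)")
  as_qvcv_panel(as.data.frame(obj$entries, stringsAsFactors = FALSE))
}

#' @rdname read_panel
#' @param panel a `qvcv_panel`.
#' @export
write_panel <- function(panel, path) {
  panel <- as_qvcv_panel(panel)
  jsonlite::write_json(
    list(format = "qvcv_panel", version = 1L,
         entries = as.data.frame(unclass(panel), stringsAsFactors = FALSE)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Serialize and restore a fitted PTA model
#'
#' The model is written as versioned JSON (full double precision) so that
#' restored models predict bit-identically.
#'
#' @param model a `qvcv_pta`.
#' @param path file path.
#' @export
write_pta_model <- function(model, path) {
  stopifnot(inherits(model, "qvcv_pta"))
  core <- model$core
  obj <- list(
    format = "qvcv_pta", version = 1L,
    lambda = model$lambda, pca_variance = model$pca_variance,
    normalization = model$normalization,
    n = model$n, feature_names = model$feature_names,
    center = unname(core$center), scale = unname(core$scale),
    rotation = core$rotation, sdev = core$sdev, k = core$k,
    intercept = core$intercept, beta = unname(core$beta),
    classifier = if (!is.null(model$classifier)) {
      list(intercept = model$classifier$intercept,
           beta = unname(model$classifier$beta))
    },
    cv = if (!is.null(model$cv)) {
      list(mae = model$cv$mae, n_repeats = model$cv$n_repeats,
           split_fraction = model$cv$split_fraction,
           seed = model$cv$seed, ppta = model$cv$ppta)
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pta_model
#' @export
read_pta_model <- function(path) {
  if (!file.exists(path)) stop_qvcv("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "qvcv_pta")) {
    stop_qvcv(path, ": not a serialized qvcv_pta model")
  }
  rot <- matrix(unlist(obj$rotation), ncol = obj$k)
  rownames(rot) <- obj$feature_names
  colnames(rot) <- paste0("PC", seq_len(obj$k))
  core <- list(center = stats::setNames(obj$center, obj$feature_names),
               scale = stats::setNames(obj$scale, obj$feature_names),
               rotation = rot, sdev = obj$sdev, k = obj$k,
               intercept = obj$intercept, beta = obj$beta, scores = NULL)
  structure(
    list(core = core, lambda = obj$lambda, pca_variance = obj$pca_variance,
         normalization = obj$normalization %||% "center",
         feature_names = obj$feature_names, n = obj$n, pta = NULL,
         fitted_training = NULL, training_mae = NA_real_,
         cv = obj$cv, classifier = obj$classifier, call = NULL),
    class = "qvcv_pta"
  )
}

# write a data frame as CSV preceded by '#' provenance comments (package
# version, seed, config hash) so re-runs are auditable and byte-identical
.write_csv_with_provenance <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("qvcv"))
  writeLines(sprintf("# qvcv %s", ver), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config)) {
    writeLines(sprintf("# config: %s", .config_hash(config)), con)
  }
  num <- vapply(df, function(col) is.double(col), logical(1))
  df[num] <- lapply(df[num], round, digits = 6)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# order-independent hash of a flat config list (no external digest
# dependency; a short sum over the deparsed key=value pairs)
.config_hash <- function(config) {
  kv <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  bytes <- utf8ToInt(kv)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%s [%08x]", kv, h)
}
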