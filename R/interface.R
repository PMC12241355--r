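#' Read a validated trial table
#'
#' Trial tables are plain CSV with a header row, UTF-8, 0-based action
#' indices, session labels as strings (PBO/MPH/SUL) and booleans as 0/1.
#' Reading validates the schema: required columns must be present with
#' coercible types; unknown columns are preserved; row order is retained.
#' Training tables are additionally checked for time ordering within each
#' subject-session-block.
#'
#' @param path CSV file path.
#' @param schema One of `"training"`, `"test"`, `"subjects"`.
#' @return A validated data.frame.
#' @export
read_trials <- function(path, schema = c("training", "test", "subjects")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- switch(schema,
    training = c(subject_id = "integer", session_label = "character",
                 block_id = "integer", set_size = "integer",
                 trial_index = "integer", stimulus_id = "integer",
                 action = "integer", correct = "integer", points = "integer"),
    test = c(subject_id = "integer", session_label = "character",
             left_stimulus = "integer", right_stimulus = "integer",
             choice = "character", rt = "numeric"),
    subjects = c(subject_id = "integer", da = "numeric"))
  miss <- setdiff(names(req), names(df))
  if (length(miss)) {
    stop(sprintf("%s table is missing required column(s): %s", schema,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) > 0) {
    for (col in names(req)) {
      coerced <- switch(req[[col]],
                        integer = suppressWarnings(as.integer(df[[col]])),
                        numeric = suppressWarnings(as.numeric(df[[col]])),
                        character = as.character(df[[col]]))
      if (req[[col]] != "character" && anyNA(coerced) && !anyNA(df[[col]])) {
        stop(sprintf("column '%s' is not %s", col, req[[col]]), call. = FALSE)
      }
      df[[col]] <- coerced
    }
    if (schema == "training") {
      key <- interaction(df$subject_id, df$session_label, df$block_id,
                         drop = TRUE)
      ok <- tapply(df$trial_index, key, function(ti) all(diff(ti) > 0))
      if (!all(ok)) {
        stop("training trials are not time-ordered within block", call. = FALSE)
      }
    }
  }
  df
}

#' Write a trial table
#'
#' @param df data.frame to write.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trials <- function(df, path) {
  df <- as.data.frame(df)
  logi <- vapply(df, is.logical, logical(1))
  df[logi] <- lapply(df[logi], as.integer)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
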