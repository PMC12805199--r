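#' Construct a multi-group binary response dataset
#'
#' Bundles an N x J binary response matrix (NA = not administered / missing)
#' with a group label per respondent. Group labels may be arbitrary strings or
#' numbers; they are mapped to contiguous indices 1..S in order of first
#' appearance, and the map is kept so reports can show original labels.
#'
#' @param responses numeric matrix (or data frame) of 0/1 responses with NA
#'   allowed; rows are respondents, columns are items.
#' @param groups length-N vector of group labels.
#' @param item_ids optional item labels (default: column names or "item1"...).
#' @param respondent_ids optional respondent labels.
#' @return An object of class `response_data` with elements `responses`
#'   (N x J matrix over 0/1/NA), `group_of` (integer 1..S), `group_labels`
#'   (original label per index), `n_s` (group sizes), `item_ids`,
#'   `respondent_ids`, and scalars `N`, `J`, `S`.
#' @examples
#' y <- matrix(c(1, 0, 1, 1, 0, 0, 1, 0), nrow = 4)
#' response_data(y, groups = c("A", "A", "B", "B"))
#' @export
response_data <- function(responses, groups, item_ids = NULL,
                          respondent_ids = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  N <- nrow(responses)
  J <- ncol(responses)
  if (length(groups) != N) {
    stop("length(groups) [", length(groups), "] != nrow(responses) [", N, "]")
  }
  bad <- which(!is.na(responses) & responses != 0 & responses != 1)
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% N) + 1
    j <- ((bad[1] - 1) %/% N) + 1
    stop("non-binary observed value ", responses[bad[1]],
         " at row ", i, ", column ", j)
  }
  group_labels <- unique(as.character(groups))
  group_of <- match(as.character(groups), group_labels)
  S <- length(group_labels)
  empty_resp <- which(rowSums(!is.na(responses)) == 0)
  if (length(empty_resp) > 0) {
    stop("respondent(s) with no observed responses: ",
         paste(utils::head(empty_resp, 5), collapse = ", "))
  }
  dead_items <- which(colSums(!is.na(responses)) == 0)
  if (is.null(item_ids)) {
    item_ids <- colnames(responses)
    if (is.null(item_ids)) item_ids <- paste0("item", seq_len(J))
  }
  if (length(dead_items) > 0) {
    stop("item(s) with no observed responses: ",
         paste(item_ids[dead_items], collapse = ", "))
  }
  if (is.null(respondent_ids)) {
    respondent_ids <- rownames(responses)
    if (is.null(respondent_ids)) respondent_ids <- as.character(seq_len(N))
  }
  dimnames(responses) <- NULL
  structure(
    list(responses = responses, group_of = as.integer(group_of),
         group_labels = group_labels,
         n_s = as.integer(tabulate(group_of, nbins = S)),
         item_ids = as.character(item_ids),
         respondent_ids = as.character(respondent_ids),
         N = N, J = J, S = S),
    class = "response_data"
  )
}

#' @export
print.response_data <- function(x, ...) {
  cat("Multi-group binary response data\n")
  cat("  respondents:", x$N, " items:", x$J, " groups:", x$S, "\n")
  cat("  group sizes:", paste(x$n_s, collapse = ", "), "\n")
  cat(sprintf("  observed cells: %.1f%%\n", 100 * mean(!is.na(x$responses))))
  invisible(x)
}

#' Read a wide-format response CSV
#'
#' The canonical input layout: one row per respondent, one column of group
#' labels, and one numeric 0/1 column per item. Anything equal to
#' `missing_token` (and empty cells) is treated as not observed.
#'
#' @param path CSV file (RFC-4180, header row required).
#' @param group_column name of the group-label column.
#' @param missing_token string marking missing responses (default "NA").
#' @param id_column optional name of a respondent-id column.
#' @return A [response_data] object.
#' @export
read_responses <- function(path, group_column = "group",
                           missing_token = "NA", id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c(missing_token, ""))
  if (!group_column %in% names(df)) {
    stop("group column '", group_column, "' not present in ", path)
  }
  groups <- df[[group_column]]
  if (anyNA(groups)) stop("missing group label in column '", group_column, "'")
  ids <- NULL
  keep <- setdiff(names(df), group_column)
  if (!is.null(id_column)) {
    ids <- df[[id_column]]
    keep <- setdiff(keep, id_column)
  }
  y <- as.matrix(df[keep])
  ynum <- suppressWarnings(matrix(as.numeric(y), nrow(y), ncol(y)))
  bad <- which(!is.na(y) & is.na(ynum))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(y)) + 1
    j <- ((bad[1] - 1) %/% nrow(y)) + 1
    stop("non-numeric response '", y[bad[1]], "' at row ", i,
         ", item '", keep[j], "'")
  }
  colnames(ynum) <- keep
  response_data(ynum, groups, item_ids = keep, respondent_ids = ids)
}

#' Read a long-format response file
#'
#' For sparse data (large item banks, adaptive administration) a long triplet
#' layout (respondent, item, response) is the natural format; unobserved
#' respondent-item combinations simply have no row.
#'
#' @param path CSV with columns for respondent id, item id, response, group.
#' @param respondent_column,item_column,response_column,group_column column
#'   names (defaults "respondent", "item", "response", "group").
#' @return A [response_data] object. The group of a respondent must be
#'   constant across that respondent's rows.
#' @export
read_responses_long <- function(path, respondent_column = "respondent",
                                item_column = "item",
                                response_column = "response",
                                group_column = "group") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(respondent_column, item_column, response_column, group_column)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  rid <- as.character(df[[respondent_column]])
  iid <- as.character(df[[item_column]])
  resp <- as.numeric(df[[response_column]])
  grp <- as.character(df[[group_column]])
  respondents <- unique(rid)
  items <- unique(iid)
  y <- matrix(NA_real_, length(respondents), length(items))
  ri <- match(rid, respondents)
  ci <- match(iid, items)
  dup <- duplicated(cbind(ri, ci))
  if (any(dup)) stop("duplicated (respondent, item) row(s), first at line ",
                     which(dup)[1] + 1L)
  y[cbind(ri, ci)] <- resp
  g_first <- grp[!duplicated(ri)][order(unique(ri))]
  grp_per_resp <- tapply(grp, ri, function(v) {
    u <- unique(v)
    if (length(u) > 1) stop("respondent with conflicting group labels")
    u
  })
  g <- as.character(grp_per_resp[as.character(seq_along(respondents))])
  response_data(y, g, item_ids = items, respondent_ids = respondents)
}

#' Write the fit report files
#'
#' Emits four plain-text artifacts for a post-processed fit: the per
#' (item, group) parameter table with cluster labels, the pairwise DIF flag
#' table, the impact table, and a JSON metadata record.
#'
#' @param result a `dif_report` from [postprocess()] or the `best` element of
#'   [select_model()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_fit_report <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    item_params = file.path(out_dir, "item_params.csv"),
    pairwise_flags = file.path(out_dir, "pairwise_flags.csv"),
    impact = file.path(out_dir, "impact.csv"),
    metadata = file.path(out_dir, "metadata.json")
  )
  # 17 significant digits so numeric values survive the CSV round trip exactly
  fmt <- function(df) {
    for (col in names(df)) {
      if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
    }
    df
  }
  utils::write.csv(fmt(result$param_table), paths["item_params"],
                   row.names = FALSE)
  utils::write.csv(result$flag_table, paths["pairwise_flags"], row.names = FALSE)
  utils::write.csv(fmt(result$impact_table), paths["impact"],
                   row.names = FALSE)
  jsonlite::write_json(result$metadata, paths["metadata"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write a response dataset as a wide CSV
#'
#' Inverse of [read_responses()]: group labels are restored from the stored
#' label map and missing entries are written as `missing_token`.
#'
#' @param data a [response_data] object.
#' @param path output CSV path.
#' @param missing_token token used for missing cells.
#' @export
write_responses <- function(data, path, missing_token = "NA") {
  df <- as.data.frame(data$responses)
  names(df) <- data$item_ids
  df <- cbind(respondent = data$respondent_ids,
              group = data$group_labels[data$group_of], df)
  utils::write.csv(df, path, row.names = FALSE, na = missing_token)
  invisible(path)
}
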