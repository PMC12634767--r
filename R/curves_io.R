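#' Kinematic curve sets and their CSV representation
#'
#' A `curve_set` holds `n` kinematic curves (one per observation) sampled on
#' a common normalized time grid: an n x K numeric matrix plus the grid, a
#' response label (angle, velocity or acceleration) and observation ids.
#'
#' @param values numeric n x K matrix, rows are observations, no missing
#'   values allowed.
#' @param grid a [time_grid()] (or numeric vector coerced to one) of length K.
#' @param response one of `"angle"`, `"velocity"`, `"acceleration"`; fixes
#'   the units (deg, deg/s, deg/s2).
#' @param ids character vector of n unique observation labels; defaults to
#'   rownames of `values` or `obs_1 ... obs_n`.
#' @return an object of class `"curve_set"` with elements `values`, `grid`,
#'   `response`, `units`, `ids`.
#' @export
curve_set <- function(values, grid,
                      response = c("angle", "velocity", "acceleration"),
                      ids = NULL) {
  response <- match.arg(response)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  grid <- as_time_grid(grid)
  if (ncol(values) != length(grid))
    stop("values has ", ncol(values), " columns but grid has ",
         length(grid), " points")
  if (nrow(values) < 1L) stop("need at least one observation")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing value in curve matrix at row ", bad[1L],
         ", column ", bad[2L])
  }
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("obs_", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values))
    stop("ids length (", length(ids), ") != number of rows (",
         nrow(values), ")")
  if (anyDuplicated(ids))
    stop("duplicated observation ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(values) <- ids
  colnames(values) <- NULL
  structure(
    list(values = values, grid = grid, response = response,
         units = c(angle = "deg", velocity = "deg/s",
                   acceleration = "deg/s2")[[response]],
         ids = ids),
    class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat("curve_set:", nrow(x$values), x$response, "curves (", x$units,
      ") on", length(x$grid), "time points\n")
  invisible(x)
}

#' @rdname curve_set
#' @param x object to test.
#' @export
is_curve_set <- function(x) inherits(x, "curve_set")

#' Read a wide-format curve matrix from CSV
#'
#' Expects a header `id,t_0001,...,t_K` (any `t_`-prefixed names accepted)
#' and one row per observation.  The grid is reconstructed as the default
#' equally spaced K-point grid on \[0, 1\].
#'
#' @param path CSV file path.
#' @param response response label passed to [curve_set()].
#' @return a [curve_set()].
#' @export
read_curve_matrix <- function(path,
                              response = c("angle", "velocity",
                                           "acceleration")) {
  response <- match.arg(response)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("curve CSV needs an id column plus at least 2 time columns: ", path)
  if (names(df)[1L] != "id")
    stop("first column of a curve CSV must be 'id', got '", names(df)[1L], "'")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric value in curve CSV, id '", ids[bad[1L]],
             "', column '", names(vals)[j], "'")
      col <- num
    }
    if (anyNA(col))
      stop("missing value in curve CSV, id '", ids[which(is.na(col))[1L]],
           "', column '", names(vals)[j], "'")
    vals[[j]] <- col
  }
  curve_set(as.matrix(vals), time_grid(ncol(vals)), response, ids = ids)
}

#' Write a curve set as a wide-format CSV
#'
#' Inverse of [read_curve_matrix()]; values are written at full double
#' precision so a read/write round trip is bitwise exact.
#'
#' @param cs a [curve_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_matrix <- function(cs, path) {
  stopifnot(is_curve_set(cs))
  K <- ncol(cs$values)
  df <- data.frame(id = cs$ids, cs$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", sprintf("t_%04d", seq_len(K)))
  write_full_precision(df, path)
  invisible(path)
}

# CSV writer keeping full double precision (17 significant digits).
write_full_precision <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) {
    x <- sprintf("%.17g", df[[j]])
    # keep integers tidy
    int <- df[[j]] == round(df[[j]]) & abs(df[[j]]) < 1e15 & !is.na(df[[j]])
    x[int] <- sprintf("%d", as.integer(round(df[[j]][int])))
    df[[j]] <- x
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a covariate table from CSV
#'
#' Expects columns `id, ndi, age, neck_length, sex`.  NDI must lie on its
#' 0-50 scale; sex is accepted as 0/1 or F/M (female, the majority group, is
#' the reference level coded 0).
#'
#' @param path CSV file path.
#' @return a `covariate_table`: a data.frame with columns `id`, `ndi`,
#'   `age`, `neck_length`, `sex`.
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  covariate_table(df)
}

#' Construct/validate a covariate table
#'
#' @param df data.frame with columns `id`, `ndi`, `age`, `neck_length`,
#'   `sex` (sex as 0/1 numeric or "F"/"M").
#' @return validated data.frame of class `"covariate_table"`.
#' @export
covariate_table <- function(df) {
  need <- c("id", "ndi", "age", "neck_length", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicated observation ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  for (v in c("ndi", "age", "neck_length")) {
    if (!is.numeric(df[[v]]))
      stop("column '", v, "' must be numeric")
    if (anyNA(df[[v]]))
      stop("missing value in column '", v, "', id '",
           df$id[which(is.na(df[[v]]))[1L]], "'")
  }
  if (any(df$ndi < 0 | df$ndi > 50))
    stop("NDI values outside the 0-50 disability scale: ",
         paste(df$id[df$ndi < 0 | df$ndi > 50], collapse = ", "))
  sx <- df$sex
  if (is.character(sx) || is.factor(sx)) {
    sx <- toupper(trimws(as.character(sx)))
    ok <- sx %in% c("F", "M", "0", "1")
    if (!all(ok))
      stop("unknown sex token(s): ", paste(unique(sx[!ok]), collapse = ", "),
           " (expected 0/1 or F/M)")
    sx <- ifelse(sx %in% c("M", "1"), 1, 0)
  } else {
    if (anyNA(sx) || !all(sx %in% c(0, 1)))
      stop("numeric sex must be coded 0 (female) / 1 (male)")
  }
  df$sex <- as.numeric(sx)
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Write a covariate table as CSV
#'
#' @param cov a covariate table (see [covariate_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariate_table <- function(cov, path) {
  write_full_precision(as.data.frame(cov), path)
  invisible(path)
}

#' Write a long-format result table as CSV
#'
#' One row per (response, coefficient, time, method) with columns
#' `beta, se, t, p_raw, p_bh, p_by` in that fixed order; numeric values at
#' full double precision.
#'
#' @param results a result table from [result_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path) {
  need <- c("response", "coefficient", "time", "method",
            "beta", "se", "t", "p_raw", "p_bh", "p_by")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("result table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(results) == 0L) stop("refusing to write an empty result table")
  write_full_precision(as.data.frame(results)[, need], path)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path CSV file path.
#' @return data.frame in the same long format.
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
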