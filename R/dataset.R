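## Gait dataset container: velocity-sorted records (v_x, Y, CoT) with CSV
## round-trip in the "v_x,cot,<56 parameter names>" layout.

#' Construct a gait dataset
#'
#' A gait dataset holds one record per admitted evaluation trial: the
#' achieved walking velocity `v_x`, the CoT, and the full 56-entry control
#' parameter vector. Records are kept sorted ascending by `v_x` (stable for
#' ties), which the moving-average CoT window relies on.
#'
#' @param v_x Numeric vector of achieved velocities (m/s, positive).
#' @param cot Numeric vector of CoT values (positive).
#' @param params Matrix (`n x 56`) of control parameters, columns in
#'   registry order (or carrying registry names).
#' @return A data.frame of class `gait_dataset` with columns `v_x`, `cot`
#'   and the 56 parameter columns.
#' @export
gait_dataset <- function(v_x, cot, params) {
  n <- length(v_x)
  if (n == 0L) {
    df <- as.data.frame(matrix(numeric(0), 0, 58))
    names(df) <- c("v_x", "cot", parameter_names())
    class(df) <- c("gait_dataset", "data.frame")
    return(df)
  }
  params <- as.matrix(params)
  stopifnot(length(cot) == n, nrow(params) == n, ncol(params) == 56L)
  if (any(v_x <= 0)) stop("v_x must be positive")
  if (any(cot <= 0)) stop("cot must be positive")
  if (is.null(colnames(params))) {
    colnames(params) <- parameter_names()
  } else {
    params <- params[, parameter_names(), drop = FALSE]
  }
  ord <- order(v_x)  # stable (radix/shell with ties kept in order)
  df <- data.frame(v_x = v_x[ord], cot = cot[ord],
                   params[ord, , drop = FALSE],
                   check.names = FALSE, row.names = NULL)
  class(df) <- c("gait_dataset", "data.frame")
  df
}

#' Extract the parameter matrix of a gait dataset
#' @param dataset A `gait_dataset`.
#' @return Numeric matrix `n x 56` in registry order.
#' @export
dataset_params <- function(dataset) {
  as.matrix(dataset[, parameter_names(), drop = FALSE])
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat("Gait dataset: ", nrow(x), " records", sep = "")
  if (nrow(x) > 0) {
    cat(", v_x in [", format(min(x$v_x), digits = 3), ", ",
        format(max(x$v_x), digits = 3), "] m/s, CoT in [",
        format(min(x$cot), digits = 3), ", ",
        format(max(x$cot), digits = 3), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Write a gait dataset to CSV
#'
#' Layout: header `v_x,cot,<56 parameter names in registry order>`, one
#' record per row, sorted ascending by `v_x`.
#'
#' @param dataset A `gait_dataset`.
#' @param path Output file path.
#' @export
write_gait_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "gait_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Read a gait dataset from CSV
#'
#' @param path CSV file in the [write_gait_dataset()] layout.
#' @return A `gait_dataset` (re-sorted by velocity on read).
#' @export
read_gait_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("v_x", "cot", parameter_names())
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("dataset file is missing column(s): ", paste(missing, collapse = ", "))
  }
  gait_dataset(df$v_x, df$cot, as.matrix(df[, parameter_names()]))
}

#' Merge gait datasets
#' @param ... `gait_dataset` objects.
#' @return A single velocity-sorted `gait_dataset`.
#' @export
merge_gait_datasets <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (!length(parts)) return(gait_dataset(numeric(0), numeric(0), NULL))
  all <- do.call(rbind, lapply(parts, as.data.frame))
  gait_dataset(all$v_x, all$cot, as.matrix(all[, parameter_names()]))
}
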