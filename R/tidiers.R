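#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an entropy table
#'
#' @param x An `entropy_result`.
#' @param ... Unused.
#' @return A plain tibble, one row per selection.
#' @method tidy entropy_result
#' @export
tidy.entropy_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.entropy_result
#' @method glance entropy_result
#' @export
glance.entropy_result <- function(x, ...) {
  tibble::tibble(
    n_selections = nrow(x),
    temperature = x$temperature[1],
    n_frames = x$n_frames[1],
    S_total_range = max(x$S_config) - min(x$S_config)
  )
}

#' Tidy a pair-force table
#'
#' @param x A `pair_force_table`.
#' @param ... Unused.
#' @method tidy pair_force_table
#' @export
tidy.pair_force_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.pair_force_table
#' @method glance pair_force_table
#' @export
glance.pair_force_table <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_attractive = sum(x$F_mean < 0),
    n_repulsive = sum(x$F_mean > 0),
    strongest = if (nrow(x)) x$F_mean[which.max(abs(x$F_mean))] else NA_real_,
    cutoff = attr(x, "cutoff") %||% NA_real_,
    threshold = attr(x, "threshold") %||% NA_real_,
    convention = attr(x, "convention") %||% NA_character_
  )
}

#' @importFrom rlang %||%
NULL

#' Write a result table as TSV
#'
#' TSV writers for the tabular results (entropy tables, force tables, time
#' series, histograms). Numbers are written with full precision in a fixed
#' format so identical analyses produce identical bytes.
#'
#' @param x A result tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 10,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
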