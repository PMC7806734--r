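#' Arm label sets for the four-arm maze
#'
#' The maze always has exactly four arms. Three label vocabularies are
#' supported: `"color"` for the LED mode (`B`lue, `G`reen, `R`ed, `W`hite),
#' `"contrast"` for the grayscale-object mode (`B`lack, `C`lear, `G`rey,
#' `W`hite) and `"generic"` (`A1`..`A4`). Labels are returned in canonical
#' (alphabetical) order, which is also the deterministic tie-break order used
#' throughout the package.
#'
#' @param mode One of `"color"`, `"contrast"`, `"generic"`.
#' @return Character vector of the four arm labels, canonically ordered.
#' @examples
#' arm_labels("color")
#' @export
arm_labels <- function(mode = c("color", "contrast", "generic")) {
  mode <- match.arg(mode)
  switch(mode,
    color    = c("B", "G", "R", "W"),
    contrast = c("B", "C", "G", "W"),
    generic  = c("A1", "A2", "A3", "A4")
  )
}

#' Maze layout: four labels and the two facing (opposite) arm pairs
#'
#' In the color configuration the blue and green arms face each other, as do
#' the red and white arms; the generic layout pairs A1/A3 and A2/A4. The
#' facing pairs partition the four labels into two disjoint pairs.
#'
#' @param mode Label vocabulary, see [arm_labels()].
#' @param facing_pairs Optional list of two character pairs overriding the
#'   default opposite-arm assignment.
#' @return An object of class `maze_layout` with elements `labels`, `mode`
#'   and `facing_pairs`.
#' @export
maze_layout <- function(mode = c("color", "contrast", "generic"),
                        facing_pairs = NULL) {
  mode <- match.arg(mode)
  labels <- arm_labels(mode)
  if (is.null(facing_pairs)) {
    facing_pairs <- switch(mode,
      color    = list(c("B", "G"), c("R", "W")),
      contrast = list(c("B", "W"), c("C", "G")),
      generic  = list(c("A1", "A3"), c("A2", "A4"))
    )
  }
  flat <- sort(unlist(facing_pairs))
  if (length(facing_pairs) != 2L || !identical(flat, sort(labels))) {
    stop("facing_pairs must partition the four arm labels into two pairs")
  }
  structure(
    list(labels = labels, mode = mode, facing_pairs = facing_pairs),
    class = "maze_layout"
  )
}

#' Enumerate the ordered (unidirectional) distinct-arm pairs
#'
#' A four-arm maze has exactly 12 ordered transitions between distinct arms.
#' Pairs are returned in canonical order: alphabetical on the origin label,
#' then on the destination label.
#'
#' @param labels Character vector of four arm labels (default color mode).
#' @return Data frame with columns `from`, `to` and `pair` (the `"from>to"`
#'   key), 12 rows.
#' @export
ordered_arm_pairs <- function(labels = arm_labels("color")) {
  stopifnot(length(labels) == 4L, !anyDuplicated(labels))
  labels <- sort(labels)
  grid <- expand.grid(to = labels, from = labels,
                      stringsAsFactors = FALSE)[, c("from", "to")]
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  grid <- grid[order(grid$from, grid$to), , drop = FALSE]
  rownames(grid) <- NULL
  grid$pair <- paste0(grid$from, ">", grid$to)
  grid
}

#' Enumerate the unordered (bidirectional) distinct-arm pairs
#'
#' A four-arm maze has exactly 6 unordered pairs of distinct arms.
#'
#' @inheritParams ordered_arm_pairs
#' @return Data frame with columns `a`, `b` (alphabetical within pair) and
#'   `pair` (the `"a:b"` key), 6 rows in canonical order.
#' @export
unordered_arm_pairs <- function(labels = arm_labels("color")) {
  stopifnot(length(labels) == 4L, !anyDuplicated(labels))
  labels <- sort(labels)
  cmb <- utils::combn(labels, 2L)
  out <- data.frame(a = cmb[1L, ], b = cmb[2L, ], stringsAsFactors = FALSE)
  out$pair <- paste0(out$a, ":", out$b)
  out
}

# key helpers shared by the transition and discriminability code
pair_key_ordered <- function(from, to) paste0(from, ">", to)
pair_key_unordered <- function(a, b) {
  paste0(pmin(a, b), ":", pmax(a, b))
}

check_arm_sequence <- function(seq, labels = NULL) {
  if (length(seq) == 0L) return(invisible(character(0)))
  if (anyNA(seq)) stop("arm sequence contains NA")
  if (!is.null(labels)) {
    bad <- setdiff(unique(seq), labels)
    if (length(bad) > 0L) {
      stop("unknown arm label(s): ", paste(bad, collapse = ", "))
    }
  }
  invisible(seq)
}
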