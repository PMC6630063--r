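#' Build a nested three-level category hierarchy
#'
#' Visual stimulus categories are organised on three nested levels of
#' granularity: 5 coarse, 10 mid and 23 fine categories. Every fine label
#' belongs to exactly one mid label and every mid label to exactly one coarse
#' label. The partition is drawn at random but is deterministic for a fixed
#' seed: each coarse class receives two mid classes, and the 23 fine classes
#' are distributed over the 10 mid classes with at least two each.
#'
#' Labels are zero-based integers (`0..4`, `0..9`, `0..22`) so that they match
#' on-disk label tables.
#'
#' @param seed integer seed controlling the random nesting.
#' @return an object of class `label_hierarchy` with components
#'   `mid_of_fine` (length-23 integer map fine -> mid) and `coarse_of_mid`
#'   (length-10 integer map mid -> coarse).
#' @examples
#' h <- make_label_hierarchy(seed = 1)
#' table(h$coarse_of_mid)          # two mids per coarse class
#' coarse_of_fine(h, 0:22)
#' @export
make_label_hierarchy <- function(seed = 1L) {
  rs <- local({
    set.seed(child_seed(seed, 101L))
    # two mid classes per coarse class, order randomised
    coarse_of_mid <- sample(rep(0:4, each = 2L))
    # fine class counts per mid: 23 = 10 * 2 + 3 extras
    sizes <- rep(2L, 10L)
    extras <- sample(10L, 3L)
    sizes[extras] <- sizes[extras] + 1L
    fine_perm <- sample(0:22)
    mid_of_fine <- integer(23L)
    pos <- 1L
    for (m in 1:10) {
      idx <- fine_perm[pos:(pos + sizes[m] - 1L)] + 1L
      mid_of_fine[idx] <- m - 1L
      pos <- pos + sizes[m]
    }
    list(coarse_of_mid = coarse_of_mid, mid_of_fine = mid_of_fine)
  })
  structure(list(mid_of_fine = rs$mid_of_fine,
                 coarse_of_mid = rs$coarse_of_mid,
                 seed = as.integer(seed)),
            class = "label_hierarchy")
}

#' Resolve fine labels to mid or coarse labels
#' @param hierarchy a `label_hierarchy`.
#' @param fine integer vector of fine labels in `0..22`.
#' @return integer vector of mid (`0..9`) or coarse (`0..4`) labels.
#' @export
mid_of_fine <- function(hierarchy, fine) {
  stopifnot(inherits(hierarchy, "label_hierarchy"), all(fine %in% 0:22))
  hierarchy$mid_of_fine[fine + 1L]
}

#' @rdname mid_of_fine
#' @export
coarse_of_fine <- function(hierarchy, fine) {
  hierarchy$coarse_of_mid[mid_of_fine(hierarchy, fine) + 1L]
}

#' @export
print.label_hierarchy <- function(x, ...) {
  cat("Three-level category hierarchy: 23 fine -> 10 mid -> 5 coarse\n")
  cat("fine per mid:", paste(tabulate(x$mid_of_fine + 1L, 10L), collapse = " "), "\n")
  cat("mid per coarse:", paste(tabulate(x$coarse_of_mid + 1L, 5L), collapse = " "), "\n")
  invisible(x)
}

# expand a fine label vector into the three-column label frame used throughout
label_frame <- function(hierarchy, fine) {
  data.frame(coarse = coarse_of_fine(hierarchy, fine),
             mid = mid_of_fine(hierarchy, fine),
             fine = as.integer(fine))
}
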