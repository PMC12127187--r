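#' Published evaluation panels shipped with the package
#'
#' The package ships the printed metric panels of a tertiary-care
#' screening evaluation as plain-text data: the glaucoma-suspect panel
#' (n = 245; accuracy, sensitivity, specificity, PPV, F1 in percent, one
#' decimal, for resident, AI and their OR-combination), the
#' retinal-disease panel (n = 395; the same metrics plus tier-restricted
#' sensitivities), and the media-opacity / cataract 2x2 contingency table
#' (n = 435). These serve as inputs to the integer reconstruction oracle
#' ([reconstruct_counts()]) and to exact agreement computations; they are
#' study-reported values, not outputs of this package.
#'
#' @return `study_glaucoma_panel()` and `study_retinal_panel()` return a
#'   list with `table` (tibble of printed percentages) and `n`;
#'   `study_opacity_counts()` returns a `confusion_matrix` oriented with
#'   the residents' cataract diagnosis as the reference rating.
#' @export
#' @examples
#' study_glaucoma_panel()$table
#' cohen_kappa(study_opacity_counts())
study_glaucoma_panel <- function() {
  path <- system.file("extdata", "glaucoma_panel.csv", package = "synopht",
                      mustWork = TRUE)
  list(table = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
       n = 245L)
}

#' @rdname study_glaucoma_panel
#' @export
study_retinal_panel <- function() {
  path <- system.file("extdata", "retinal_panel.csv", package = "synopht",
                      mustWork = TRUE)
  list(table = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
       n = 395L)
}

#' @rdname study_glaucoma_panel
#' @export
study_opacity_counts <- function() {
  path <- system.file("extdata", "opacity_counts.csv", package = "synopht",
                      mustWork = TRUE)
  counts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cell <- function(res, ai) {
    counts$count[counts$resident_cataract == res & counts$ai_opacity == ai]
  }
  confusion_matrix(
    tp = cell(TRUE, TRUE), fp = cell(FALSE, TRUE),
    fn = cell(TRUE, FALSE), tn = cell(FALSE, FALSE)
  )
}
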