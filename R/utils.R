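# Small unit helpers.

#' Moisture-content basis conversions
#'
#' Dry basis (kg water per kg dry solid) versus wet basis (kg water per kg
#' total mass): `w = X / (1 + X)` and `X = w / (1 - w)`.
#'
#' @param X Moisture content, dry basis (kg/kg).
#' @param w Moisture content, wet basis (fraction of total mass).
#' @return The converted moisture content.
#' @examples
#' moisture_db_to_wb(0.25)  # 0.20
#' @export
moisture_db_to_wb <- function(X) {
  if (any(X < 0)) stop("dry-basis moisture must be >= 0", call. = FALSE)
  X / (1 + X)
}

#' @rdname moisture_db_to_wb
#' @export
moisture_wb_to_db <- function(w) {
  if (any(w < 0 | w >= 1))
    stop("wet-basis moisture must lie in [0, 1)", call. = FALSE)
  w / (1 - w)
}
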