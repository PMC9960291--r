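#' Registry of published mechanical-loading prediction equations
#'
#' Twelve fixed-coefficient linear equations predicting peak ground reaction
#' force (pGRF, N) from peak acceleration (pACC, g) or peak loading rate
#' (pLR, N/s) from peak acceleration rate (pAR, g/s), together with body
#' mass (kg) and the predictor-by-mass interaction:
#' `outcome = b0 + b1 * predictor + b2 * mass + b3 * predictor * mass`.
#' One equation exists for each combination of outcome, signal vector
#' (resultant or vertical) and accelerometer placement (ankle, lower back,
#' hip). The coefficients are immutable published values.
#'
#' @return A data.frame with 12 rows and columns `outcome`, `vector`,
#'   `placement`, `b0`, `b1`, `b2`, `b3`.
#' @export
#' @examples
#' loading_models()
loading_models <- function() {
  df <- rbind(
    data.frame(outcome = "pGRF", vector = "resultant",
               placement = c("ankle", "lower_back", "hip"),
               b0 = c(1551.020, -350.125, -493.877),
               b1 = c(-132.384, 152.952, 188.759),
               b2 = c(7.927, 22.618, 18.008),
               b3 = c(2.415, 0.654, 1.279)),
    data.frame(outcome = "pGRF", vector = "vertical",
               placement = c("ankle", "lower_back", "hip"),
               b0 = c(1662.525, -287.919, -786.169),
               b1 = c(-196.301, 131.396, 177.403),
               b2 = c(8.515, 24.338, 23.953),
               b3 = c(3.169, 0.642, 1.355)),
    data.frame(outcome = "pLR", vector = "resultant",
               placement = c("ankle", "lower_back", "hip"),
               b0 = c(71932.438, -1161.976, 5118.300),
               b1 = c(-218.268, 22.804, 33.054),
               b2 = c(74.463, 624.413, 346.667),
               b3 = c(3.474, 2.135, 2.835)),
    data.frame(outcome = "pLR", vector = "vertical",
               placement = c("ankle", "lower_back", "hip"),
               b0 = c(58864.225, 8303.550, -11471.926),
               b1 = c(-194.575, -19.708, 15.332),
               b2 = c(142.545, 685.299, 691.269),
               b3 = c(3.733, 1.900, 2.670))
  )
  df$predictor <- ifelse(df$outcome == "pGRF", "pACC_g", "pAR_gs")
  df
}

#' Look up one prediction equation
#'
#' @param outcome `"pGRF"` or `"pLR"`.
#' @param vector `"resultant"` or `"vertical"`.
#' @param placement `"ankle"`, `"lower_back"` or `"hip"`.
#' @return A `loading_model` list with elements `outcome`, `vector`,
#'   `placement`, `predictor` (the summary column the equation consumes) and
#'   coefficients `b0`, `b1`, `b2`, `b3`.
#' @export
#' @examples
#' get_model("pGRF", "resultant", "hip")$b1
get_model <- function(outcome, vector, placement) {
  reg <- loading_models()
  hit <- reg$outcome == outcome & reg$vector == vector & reg$placement == placement
  if (sum(hit) != 1) {
    stop(sprintf("lookup error: no equation for (%s, %s, %s)", outcome, vector, placement),
         call. = FALSE)
  }
  structure(as.list(reg[hit, , drop = FALSE]), class = "loading_model")
}

#' @export
print.loading_model <- function(x, ...) {
  unit <- if (x$outcome == "pGRF") "N" else "N/s"
  pred <- if (x$outcome == "pGRF") "pACC" else "pAR"
  cat(sprintf("<loading_model> %s (%s) = %.3f %+.3f(%s) %+.3f(body mass) %+.3f(%s x body mass)  [%s, %s]\n",
              x$outcome, unit, x$b0, x$b1, pred, x$b2, x$b3, pred, x$vector, x$placement))
  invisible(x)
}

#' Evaluate a prediction equation
#'
#' `b0 + b1 * predictor + b2 * mass + b3 * predictor * mass`, in double
#' precision. The predictor is pACC in g for pGRF equations and pAR in g/s
#' for pLR equations; mass is in kg; the output is in N or N/s. Negative
#' predictions (possible at implausible inputs) are returned as-is with a
#' warning and flagged in the `"negative"` attribute, never clamped.
#'
#' @param model A `loading_model` from [get_model()].
#' @param predictor_value pACC (g) or pAR (g/s); non-negative, vectorized.
#' @param body_mass_kg Body mass in kg, vectorized.
#' @return Numeric vector of predicted loading values with a logical
#'   `"negative"` attribute.
#' @export
#' @examples
#' m <- get_model("pGRF", "resultant", "hip")
#' predict_loading(m, predictor_value = 5, body_mass_kg = 80)
predict_loading <- function(model, predictor_value, body_mass_kg) {
  stopifnot(inherits(model, "loading_model"))
  p <- as.double(predictor_value)
  m <- as.double(body_mass_kg)
  if (any(!is.finite(p)) || any(!is.finite(m))) {
    stop("input error: predictor and body mass must be finite", call. = FALSE)
  }
  out <- model$b0 + model$b1 * p + model$b2 * m + model$b3 * p * m
  neg <- out < 0
  if (any(neg)) {
    warning(sprintf("%d prediction(s) are negative; returned unclamped", sum(neg)),
            call. = FALSE)
  }
  attr(out, "negative") <- neg
  out
}

#' Apply the equation registry to a summary table
#'
#' One prediction per row, using the equation matching the requested outcome
#' and vector and that row's accelerometer placement. Row order is preserved.
#'
#' @param summaries A summary data.frame (see [write_summary_table()] for
#'   the column contract).
#' @param outcome `"pGRF"` or `"pLR"`.
#' @param vector `"resultant"` or `"vertical"`.
#' @return `summaries` with an added `predicted` column (N or N/s).
#' @export
predict_table <- function(summaries, outcome, vector) {
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) == 0) {
    summaries$predicted <- numeric(0)
    return(summaries)
  }
  if (!"body_mass_kg" %in% names(summaries) || anyNA(summaries$body_mass_kg)) {
    bad <- if ("body_mass_kg" %in% names(summaries)) which(is.na(summaries$body_mass_kg))[1] else 1L
    stop(sprintf("input error: missing body mass (row %d)", bad), call. = FALSE)
  }
  pred_col <- if (outcome == "pGRF") "pACC_g" else "pAR_gs"
  out <- numeric(nrow(summaries))
  for (pl in unique(summaries$placement)) {
    model <- get_model(outcome, vector, pl)
    rows <- summaries$placement == pl
    out[rows] <- suppressWarnings(
      as.numeric(predict_loading(model, summaries[[pred_col]][rows],
                                 summaries$body_mass_kg[rows]))
    )
  }
  summaries$predicted <- out
  summaries
}

#' Dump the equation registry as JSON
#'
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
dump_registry_json <- function(path = NULL) {
  js <- jsonlite::toJSON(loading_models(), digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
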