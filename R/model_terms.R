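# The 13 predictor terms of the abundance model and the strong-heredity
# rule that gates higher-order terms on their parent linear terms.

#' Predictor terms of the abundance model
#'
#' Thirteen terms (excluding the intercept) in the fixed design-matrix
#' order: linear NAO, bathymetry, slope, distance, wind, wave and latitude;
#' quadratics in bathymetry, distance, wind and wave; and the NAO x
#' bathymetry and NAO x distance interactions. Each higher-order term lists
#' the linear parents whose inclusion indicators gate it (strong heredity).
#'
#' @return data.frame with columns `name`, `order` (`linear`, `quadratic`,
#'   `interaction`) and list-column `parents`.
#' @export
model_terms <- function() {
  tm <- data.frame(
    name = c("nao", "bathy", "bathy2", "slope", "dist", "dist2",
             "wind", "wind2", "wave", "wave2", "latitude",
             "nao_x_bathy", "nao_x_dist"),
    order = c("linear", "linear", "quadratic", "linear", "linear",
              "quadratic", "linear", "quadratic", "linear", "quadratic",
              "linear", "interaction", "interaction"),
    stringsAsFactors = FALSE
  )
  tm$parents <- list(character(0), character(0), "bathy", character(0),
                     character(0), "dist", character(0), "wind",
                     character(0), "wave", character(0),
                     c("nao", "bathy"), c("nao", "dist"))
  validate_terms(tm)
  tm
}

# structural checks on a term table: parents exist, are linear, and the
# parent count matches the term order
validate_terms <- function(terms) {
  stopifnot(all(c("name", "order", "parents") %in% names(terms)))
  if (anyDuplicated(terms$name)) stop("duplicate term names")
  n_par <- lengths(terms$parents)
  bad <- (terms$order == "linear" & n_par != 0) |
    (terms$order == "quadratic" & n_par != 1) |
    (terms$order == "interaction" & n_par != 2)
  if (any(bad))
    stop("terms with wrong parent count: ", paste(terms$name[bad], collapse = ", "))
  for (i in seq_len(nrow(terms))) {
    for (p in terms$parents[[i]]) {
      j <- match(p, terms$name)
      if (is.na(j)) stop("term '", terms$name[i], "': unknown parent '", p, "'")
      if (terms$order[j] != "linear")
        stop("term '", terms$name[i], "': parent '", p, "' is not a linear term")
    }
  }
  invisible(terms)
}

#' Heredity-adjusted inclusion indicators
#'
#' Applies the strong-heredity rule: the adjusted indicator of term k is the
#' product of its own indicator and the indicators of all its parent linear
#' terms, so for an interaction `gamma_adj[12] = gamma[1] * gamma[2] *
#' gamma[12]`. Linear terms pass through unchanged.
#'
#' @param gamma binary vector, one indicator per term.
#' @param terms term table from [model_terms()].
#' @return Binary vector of adjusted indicators.
#' @export
heredity_adjust <- function(gamma, terms = model_terms()) {
  if (length(gamma) != nrow(terms))
    stop("gamma has length ", length(gamma), " but there are ", nrow(terms), " terms")
  if (!all(gamma %in% c(0, 1))) stop("gamma must be binary")
  adj <- gamma
  for (i in seq_len(nrow(terms))) {
    for (p in terms$parents[[i]])
      adj[i] <- adj[i] * gamma[match(p, terms$name)]
  }
  adj
}
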