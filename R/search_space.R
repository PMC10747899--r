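# Hyperparameter search space: mixed continuous/integer box, decoded into
# concrete RNN training parameters. Optimizers work on raw real vectors; all
# integer handling happens at decode time so velocity arithmetic stays exact.

#' Create a single parameter specification
#'
#' @param name Identifier for the dimension.
#' @param lower,upper Numeric bounds with `lower < upper`.
#' @param kind `"continuous"` or `"integer"`. Integer dimensions are still
#'   searched as reals and rounded to the nearest whole number at decode.
#' @return A `parameter_spec` object.
#' @export
parameter_spec <- function(name, lower, upper, kind = c("continuous", "integer")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1L ||
      length(upper) != 1L || !(lower < upper)) {
    stop("parameter_spec: 'lower' must be strictly less than 'upper'")
  }
  structure(
    list(name = name, lower = as.numeric(lower), upper = as.numeric(upper),
         kind = kind),
    class = "parameter_spec"
  )
}

#' Assemble a search space from parameter specifications
#'
#' @param specs List of [parameter_spec()] objects, in encoding order.
#' @return A `search_space` object with a `dimension` field.
#' @export
search_space <- function(specs) {
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "parameter_spec")))
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("search_space: duplicate parameter names")
  structure(list(specs = specs, dimension = length(specs)),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("search_space with", x$dimension, "dimensions\n")
  for (s in x$specs) {
    cat(sprintf("  %-14s [%g, %g] %s\n", s$name, s$lower, s$upper, s$kind))
  }
  invisible(x)
}

#' Default 7-dimensional RNN hyperparameter space
#'
#' Encodes learning rate, dropout fraction, training epochs, recurrent layer
#' count and one neuron-count slot per possible layer (up to 3). The vector
#' is fixed-length so every swarm agent shares a dimension; neuron slots
#' beyond the decoded layer count are carried but ignored.
#'
#' Bounds: learning rate in \[1e-4, 0.01\], dropout in \[0.05, 0.2\], epochs
#' in \[30, 60\], layers in \[1, 3\], each neuron count in \[8, 15\]
#' (half the lag count up to the lag count, for 15 lags).
#'
#' @return A `search_space` with `dimension = 7`.
#' @export
default_space <- function() {
  search_space(list(
    parameter_spec("learning_rate", 1e-4, 0.01, "continuous"),
    parameter_spec("dropout", 0.05, 0.2, "continuous"),
    parameter_spec("epochs", 30, 60, "integer"),
    parameter_spec("num_layers", 1, 3, "integer"),
    parameter_spec("neurons_1", 8, 15, "integer"),
    parameter_spec("neurons_2", 8, 15, "integer"),
    parameter_spec("neurons_3", 8, 15, "integer")
  ))
}

#' Clip a raw position into the search box
#'
#' @param position Numeric vector of length `space$dimension`.
#' @param space A `search_space`.
#' @return The component-wise clipped vector; in-bounds components are
#'   returned unchanged.
#' @export
clip_to_bounds <- function(position, space) {
  check_position(position, space)
  lo <- vapply(space$specs, `[[`, numeric(1), "lower")
  hi <- vapply(space$specs, `[[`, numeric(1), "upper")
  pmin(pmax(as.numeric(position), lo), hi)
}

check_position <- function(position, space) {
  if (!is.numeric(position) || length(position) != space$dimension) {
    stop(sprintf("position has length %d but the search space has dimension %d",
                 length(position), space$dimension))
  }
  invisible(TRUE)
}

#' Decode an optimizer position into RNN hyperparameters
#'
#' Integer dimensions are rounded to the nearest whole number; only the
#' first `num_layers` neuron slots are read. Positions are clipped to the
#' box first, so any real vector of the right length decodes.
#'
#' @param position Numeric vector of length `space$dimension`.
#' @param space A `search_space`, by default [default_space()].
#' @return A `hyperparameter_set` with fields `learning_rate`, `dropout`,
#'   `epochs`, `num_layers` and `neurons` (length `num_layers`).
#' @examples
#' decode_position(c(0.007225, 0.150573, 58, 1, 12, 10, 9))
#' @export
decode_position <- function(position, space = default_space()) {
  check_position(position, space)
  pos <- clip_to_bounds(position, space)
  val <- numeric(space$dimension)
  for (i in seq_along(space$specs)) {
    s <- space$specs[[i]]
    val[i] <- if (s$kind == "integer") {
      min(max(round(pos[i]), ceiling(s$lower)), floor(s$upper))
    } else pos[i]
  }
  names(val) <- vapply(space$specs, `[[`, character(1), "name")
  num_layers <- as.integer(val[["num_layers"]])
  neurons <- as.integer(val[paste0("neurons_", seq_len(num_layers))])
  hyperparameter_set(
    learning_rate = val[["learning_rate"]],
    dropout = val[["dropout"]],
    epochs = as.integer(val[["epochs"]]),
    num_layers = num_layers,
    neurons = neurons
  )
}

#' Construct a validated hyperparameter set
#'
#' @param learning_rate Gradient step size.
#' @param dropout Dropout fraction applied after each recurrent layer.
#' @param epochs Maximum training epochs.
#' @param num_layers Number of stacked recurrent layers.
#' @param neurons Integer vector of units per layer, length `num_layers`.
#' @return A `hyperparameter_set` object.
#' @export
hyperparameter_set <- function(learning_rate, dropout, epochs, num_layers,
                               neurons) {
  stopifnot(length(neurons) == num_layers,
            learning_rate > 0, dropout >= 0, dropout < 1,
            epochs >= 1, num_layers >= 1, all(neurons >= 1))
  structure(
    list(learning_rate = as.numeric(learning_rate),
         dropout = as.numeric(dropout),
         epochs = as.integer(epochs),
         num_layers = as.integer(num_layers),
         neurons = as.integer(neurons)),
    class = "hyperparameter_set"
  )
}

#' @export
print.hyperparameter_set <- function(x, ...) {
  cat(sprintf("hyperparameters: lr=%g dropout=%g epochs=%d layers=%d neurons=[%s]\n",
              x$learning_rate, x$dropout, x$epochs, x$num_layers,
              paste(x$neurons, collapse = ", ")))
  invisible(x)
}

#' Load search-space overrides from a YAML config file
#'
#' The file may hold a top-level `search_space:` list whose entries carry
#' `name`, `lower`, `upper` and optional `kind`. Named entries replace the
#' matching default dimension; the remaining defaults are kept, preserving
#' encoding order.
#'
#' @param path Path to a YAML file.
#' @return A `search_space`.
#' @export
space_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_space()
  overrides <- cfg$search_space
  if (is.null(overrides)) return(base)
  specs <- base$specs
  nms <- vapply(specs, `[[`, character(1), "name")
  for (ov in overrides) {
    if (is.null(ov$name)) stop("search_space override entries need a 'name'")
    i <- match(ov$name, nms)
    if (is.na(i)) stop("unknown search-space parameter: ", ov$name)
    old <- specs[[i]]
    specs[[i]] <- parameter_spec(
      name = old$name,
      lower = if (is.null(ov$lower)) old$lower else ov$lower,
      upper = if (is.null(ov$upper)) old$upper else ov$upper,
      kind = if (is.null(ov$kind)) old$kind else ov$kind
    )
  }
  search_space(specs)
}
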