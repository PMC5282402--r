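# GeometryConfig construction and radii lookups.

#' Read a geometry configuration from YAML
#'
#' The file must provide \code{thresholds}, \code{options} and \code{radii}
#' maps; missing entries fall back to the shipped defaults, so a user config
#' needs to list only the values it overrides.
#'
#' @param path path to a YAML file (see
#'   \code{system.file("extdata", "geometry_config.yaml", package = "pdbSIFt")}
#'   for the schema).
#' @return a validated \code{\link{GeometryConfig-class}} object.
#' @export
readGeometryConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- if (identical(path, .defaultConfigPath())) {
    list(thresholds = list(), options = list(), radii = list())
  } else {
    d <- defaultGeometryConfig()
    list(
      thresholds = as.list(d@thresholds),
      options = d@options,
      radii = .radiiToList(d@radii)
    )
  }
  th <- utils::modifyList(base$thresholds, raw$thresholds %||% list())
  op <- utils::modifyList(base$options, raw$options %||% list())
  rd <- utils::modifyList(base$radii, raw$radii %||% list())
  radii <- data.frame(
    element = toupper(names(rd)),
    cov = vapply(rd, function(e) as.numeric(e$cov), 0),
    vdw = vapply(rd, function(e) as.numeric(e$vdw), 0),
    stringsAsFactors = FALSE
  )
  rownames(radii) <- NULL
  new("GeometryConfig",
      thresholds = unlist(th),
      radii = radii,
      options = op)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.radiiToList <- function(radii) {
  out <- lapply(seq_len(nrow(radii)),
                function(i) list(cov = radii$cov[i], vdw = radii$vdw[i]))
  names(out) <- radii$element
  out
}

.defaultConfigPath <- function() {
  system.file("extdata", "geometry_config.yaml", package = "pdbSIFt",
              mustWork = TRUE)
}

.configCache <- new.env(parent = emptyenv())

#' Default geometry configuration
#'
#' Loads the threshold set shipped with the package (HBPLUS/CREDO-lineage
#' values; see the methods vignette for each default and its rationale).
#'
#' @return a \code{\link{GeometryConfig-class}} object.
#' @export
defaultGeometryConfig <- function() {
  if (is.null(.configCache$default)) {
    .configCache$default <- readGeometryConfig(.defaultConfigPath())
  }
  .configCache$default
}

# Coerce a path / NULL / GeometryConfig argument into a GeometryConfig.
.asConfig <- function(config) {
  if (is.null(config)) return(defaultGeometryConfig())
  if (is(config, "GeometryConfig")) return(config)
  if (is.character(config) && length(config) == 1) {
    return(readGeometryConfig(config))
  }
  stop("config must be a GeometryConfig, a YAML path, or NULL")
}

#' Look up covalent and van der Waals radii
#'
#' @param elements character vector of element symbols.
#' @param config a \code{GeometryConfig}.
#' @param strict if TRUE, unknown elements raise an error naming the element;
#'   otherwise they fall back to carbon radii with a warning.
#' @return data.frame with columns \code{cov} and \code{vdw}, one row per
#'   input element.
#' @export
lookupRadii <- function(elements, config = defaultGeometryConfig(),
                        strict = FALSE) {
  r <- config@radii
  idx <- match(toupper(elements), r$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    if (strict) {
      stop("no radii entry for element(s): ", paste(bad, collapse = ", "))
    }
    warning("no radii entry for element(s): ", paste(bad, collapse = ", "),
            "; using carbon radii", call. = FALSE)
    idx[is.na(idx)] <- match("C", r$element)
  }
  data.frame(cov = r$cov[idx], vdw = r$vdw[idx])
}

# Shorthand threshold accessor.
.th <- function(config, name) {
  v <- config@thresholds[[name]]
  if (is.null(v)) stop("GeometryConfig has no threshold named ", name)
  v
}
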