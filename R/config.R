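#' Read a kernel specification from a YAML config file
#'
#' The config maps the kernel's parameters to named keys:
#' \preformatted{
#' selection_free:
#'   family: exponential      # exponential | gaussian | uniform | delta
#'   rate: 0.2                # lambda, for exponential
#'   sd: 1.0                  # for gaussian
#'   kappa: 0                 # turn-angle concentration
#'   tau: 1                   # step duration
#' study_area: landscape.asc  # raster defining the grid (optional if every
#'                            # covariate layer fixes the grid)
#' covariates:
#'   - name: resource
#'     kind: end              # end | start | dist_end | dist_start
#'     path: resource.asc     # raster path (end/start kinds)
#'     beta: 1.5
#'   - name: den
#'     kind: dist_end
#'     point: [50, 50]
#'     beta: -0.2
#' }
#' Raster paths are resolved relative to the config file's directory.
#'
#' @param path YAML file path.
#' @return A [kernel_spec()].
#' @export
read_kernel_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  sf <- cfg$selection_free %||% stopf("config is missing 'selection_free'")
  psi <- selection_free_kernel(
    family = sf$family %||% "exponential",
    rate = sf$rate, sd = sf$sd,
    kappa = sf$kappa %||% 0, tau = sf$tau %||% 1)
  covs <- list(); beta <- numeric()
  area <- NULL
  if (!is.null(cfg$study_area))
    area <- as_study_area(read_raster(resolve(cfg$study_area)))
  for (cv in cfg$covariates %||% list()) {
    kind <- cv$kind %||% "end"
    if (kind %in% c("end", "start")) {
      layer <- read_raster(resolve(cv$path %||%
        stopf("covariate '%s' needs a raster 'path'", cv$name)))
      if (is.null(area)) area <- as_study_area(layer)
      covs <- c(covs, list(covariate(cv$name %||% "covariate", kind,
                                     layer = layer)))
    } else if (kind %in% c("dist_end", "dist_start")) {
      covs <- c(covs, list(covariate(cv$name %||% "covariate", kind,
                                     point = unlist(cv$point))))
    } else stopf("unsupported covariate kind '%s' in config", kind)
    beta <- c(beta, cv$beta %||% stopf("covariate '%s' needs a 'beta'", cv$name))
  }
  if (is.null(area))
    stopf("config must provide 'study_area' or at least one raster covariate")
  kernel_spec(psi, covs, beta, area)
}
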