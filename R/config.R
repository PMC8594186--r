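#' Read an analysis configuration file
#'
#' YAML configuration naming the parameter constraint, the change-point
#' boundaries (in generations) and the substitution-rate conversion
#' constant, plus optional root-treatment settings and the activity
#' binarization threshold. Example:
#'
#' ```yaml
#' constraint: mu0=mu1=0
#' change_points_gen: [140, 4720]
#' subst_rate: 2.5e-8
#' threshold: 25
#' root_mode: weighted
#' condition_on_survival: false
#' ```
#'
#' @param path Path to a YAML file.
#' @return A list with `constraint` (a [model_constraint()]),
#'   `change_points_gen` (numeric, possibly empty), `conv` (a
#'   [unit_conversion()]), `threshold`, and `root` (a [root_options()]).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  builtin <- builtin_constraints()
  cid <- cfg$constraint %||% "unconstrained"
  if (!cid %in% names(builtin)) {
    stop("unknown constraint '", cid, "'; available: ",
         paste(names(builtin), collapse = ", "))
  }
  list(
    constraint = builtin[[cid]],
    change_points_gen = as.numeric(cfg$change_points_gen %||% numeric(0)),
    conv = unit_conversion(cfg$subst_rate %||% 2.5e-8),
    threshold = cfg$threshold %||% 25,
    root = root_options(mode = cfg$root_mode %||% "weighted",
                        condition_on_survival =
                          isTRUE(cfg$condition_on_survival))
  )
}
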