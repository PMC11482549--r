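#' Staged equivalent-circuit presets
#'
#' Barrier-on-chip devices are characterised incrementally: (i) the chip with
#' culture medium and cell-free hydrogel matrix, (ii) plus astrocytes and
#' microglia in the matrix, (iii) plus endothelial cells on the sensing
#' electrode with matrix and brain cells lumped into one block, and (iv) the
#' complete model in which the endothelial barrier appears as its own
#' resistor/CPE block. The barrier resistor is named `R_TEER` (its parallel
#' CPE `CPE_BBB`) so it cannot collide with the stage-ii brain-cell elements.
#'
#' Canonical topologies (series chains; `[a || b]` is a parallel block):
#' \describe{
#'   \item{i}{`CPE_electrode - R_medium - [R_matrix || CPE_matrix]`}
#'   \item{ii}{stage i with `[R_cells || CPE_cells]` appended in series}
#'   \item{iii}{`CPE_cells_E - R_medium - [R_matrix_cells || CPE_matrix_cells]`}
#'   \item{iv}{`CPE_cells_E - R_medium - [R_TEER || CPE_BBB] -
#'     [R_matrix_cells || CPE_matrix_cells]`}
#' }
#'
#' @param stage One of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param parameters Named numeric vector/list covering exactly the stage's
#'   parameter names (see [stage_parameter_names()]).
#' @param topology Optional `eis_circuit` overriding the canonical wiring;
#'   its parameter names then define the contract.
#' @return A `stage_preset`: list with `stage` and bound `model`.
#' @examples
#' p <- stage_preset("i", c(CPE_electrode_Q = 1e-5, CPE_electrode_n = 0.85,
#'                          R_medium = 500, R_matrix = 5000,
#'                          CPE_matrix_Q = 1e-6, CPE_matrix_n = 0.9))
#' circuit_impedance(p$model, frequency_grid())
#' @export
stage_preset <- function(stage = c("i", "ii", "iii", "iv"), parameters,
                         topology = NULL) {
  stage <- match.arg(stage)
  skeleton <- if (is.null(topology)) stage_topology(stage) else topology
  need <- circuit_parameter_names(skeleton)
  parameters <- unlist(parameters)
  missing <- setdiff(need, names(parameters))
  extra <- setdiff(names(parameters), need)
  if (length(missing) || length(extra)) {
    stop("stage ", stage, " parameter map mismatch",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(stage = stage,
                 model = set_parameters(skeleton, parameters)),
            class = "stage_preset")
}

# Canonical wiring with placeholder values; real values are bound by
# set_parameters(). Placeholders are valid so the tree invariants hold.
stage_topology <- function(stage) {
  pblock <- function(rname, cname) {
    circuit_parallel(resistor(rname, 1), cpe(cname, 1, 0.9))
  }
  switch(stage,
    i = circuit_series(cpe("CPE_electrode", 1, 0.9), resistor("R_medium", 1),
                       pblock("R_matrix", "CPE_matrix")),
    ii = circuit_series(cpe("CPE_electrode", 1, 0.9), resistor("R_medium", 1),
                        pblock("R_matrix", "CPE_matrix"),
                        pblock("R_cells", "CPE_cells")),
    iii = circuit_series(cpe("CPE_cells_E", 1, 0.9), resistor("R_medium", 1),
                         pblock("R_matrix_cells", "CPE_matrix_cells")),
    iv = circuit_series(cpe("CPE_cells_E", 1, 0.9), resistor("R_medium", 1),
                        pblock("R_TEER", "CPE_BBB"),
                        pblock("R_matrix_cells", "CPE_matrix_cells")),
    stop("unknown stage: ", stage, call. = FALSE)
  )
}

#' @rdname stage_preset
#' @export
stage_parameter_names <- function(stage = c("i", "ii", "iii", "iv")) {
  circuit_parameter_names(stage_topology(match.arg(stage)))
}

#' @export
print.stage_preset <- function(x, ...) {
  cat(sprintf("<stage_preset %s: elements %s>\n", x$stage,
              paste(circuit_leaf_names(x$model), collapse = ", ")))
  invisible(x)
}
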