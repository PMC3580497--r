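# Shared fixtures, all built in code.

# 10-molecule fingerprint fixture with feature-set sizes frozen from an
# independent reference implementation of the circular fingerprint
# (radius 2, sparse identifiers), plus methanol for the duplicate-environment
# edge case.
fp_fixture <- function() {
  data.frame(
    smiles = c("CCO", "CC(C)O", "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1",
               "c1ccncc1", "c1ccc2ccccc2c1", "CC(=O)Oc1ccccc1C(=O)O",
               "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "NS(=O)(=O)c1ccc(Cl)cc1", "CO"),
    n_features = c(6, 6, 3, 11, 11, 9, 8, 25, 26, 18, 3),
    stringsAsFactors = FALSE
  )
}

# minimal 96-well layout: n compounds then controls, row-major
tiny_layout <- function(n_compounds = 4, n_controls = 4,
                        plate_id = "P1", ids = NULL) {
  wells <- plate_wells(96)[seq_len(n_compounds + n_controls)]
  plate_layout(plate_id, data.frame(
    well = wells,
    role = c(rep("compound", n_compounds), rep("solvent_control", n_controls)),
    compound_id = c(ids %||% sprintf("C%d", seq_len(n_compounds)),
                    rep(NA, n_controls)),
    dose_uM = c(rep(25, n_compounds), rep(NA, n_controls))
  ))
}

# write a growth table for the given layout where every well follows the
# supplied od function(well_index) -> numeric vector over `times`
write_tiny_growth <- function(path, layout, times, od_fun) {
  active <- layout$wells[layout$wells$role != "empty", ]
  lines <- c(paste(c("well", paste0("t", times)), collapse = ","))
  for (i in seq_len(nrow(active))) {
    lines <- c(lines, paste(c(active$well[i], od_fun(i)), collapse = ","))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact AUC ratio of the planted-inhibition logistic model under baseline
# subtraction: closed-form antiderivative of the logistic term, independent
# of the package's trapezoid path
closed_form_ratio <- function(phi, K = 0.9, r = 0.15, tm = 30, duration = 80) {
  one <- function(phi) {
    rp <- r * (0.5 + 0.5 * phi)
    Kp <- K * phi
    if (phi == 0) return(0)
    antider <- function(t) Kp / rp * log(1 + exp(rp * (t - tm)))
    (antider(duration) - antider(0)) -
      duration * (Kp / (1 + exp(rp * tm)))
  }
  one(phi) / one(1)
}
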