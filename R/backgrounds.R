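#' Unliganded gating constant at a different membrane potential
#'
#' L0 is voltage dependent: depolarization by `e_fold_mV` (default 60 mV)
#' reduces it e-fold, so
#' `L0(V) = L0_ref * exp(-(V - V_ref)/e_fold_mV)`.
#'
#' @param L0_ref reference unliganded gating constant.
#' @param V_ref reference membrane potential (mV).
#' @param V target membrane potential (mV).
#' @param e_fold_mV depolarization producing an e-fold reduction (mV, > 0).
#' @return L0 at `V`.
#' @examples
#' l0_at_voltage(7.4e-7, -100, -40)  # one e-fold down
#' @export
l0_at_voltage <- function(L0_ref, V_ref, V, e_fold_mV = 60) {
  check_positive(L0_ref, "L0_ref")
  check_positive(e_fold_mV, "e_fold_mV")
  L0_ref * exp(-(V - V_ref) / e_fold_mV)
}

#' Combined L0 fold change of a background-mutation set
#'
#' Background mutations far from the binding sites change only L0; assuming
#' no interaction their effects multiply.  The shipped fold table carries
#' eS450W (1.0: compensates the gating effect of depolarizing from -100 to
#' +70 mV, so no residual L0 change), eL269F (179), eE181W (5.5) and
#' dV269A (250); it can be extended or overridden via `fold_table`.
#'
#' @param mutations character vector of mutation identifiers (empty vector
#'   means no background, fold 1); a single string may combine mutations
#'   with `+`.
#' @param fold_table named numeric vector or list mapping mutation to fold.
#' @return combined fold (product of member folds).
#' @examples
#' background_fold(c("eL269F", "eE181W", "dV269A"))  # ~2.5e5
#' @export
background_fold <- function(mutations, fold_table = default_fold_table()) {
  fold_table <- unlist(fold_table)
  mutations <- mutations[!is.na(mutations)]
  if (length(mutations) == 1L && grepl("\\+", mutations))
    mutations <- strsplit(mutations, "\\+")[[1]]
  mutations <- trimws(mutations[nzchar(trimws(mutations))])
  if (length(mutations) == 0L) return(1.0)
  unknown <- setdiff(mutations, names(fold_table))
  if (length(unknown) > 0)
    stop("unknown background mutation(s): ", paste(unknown, collapse = ", "))
  folds <- fold_table[mutations]
  check_positive(folds, "fold_table entries")
  prod(folds)
}

#' @rdname background_fold
#' @export
default_fold_table <- function() {
  unlist(crceta_constants()$fold_table)
}

#' Correct an apparent di-liganded gating constant for the background
#'
#' A background that raises L0 by `fold` raises the measured (apparent) L2
#' by the same factor; dividing restores the wild-type scale.
#'
#' @param L2_apparent gating constant measured in the background construct.
#' @param fold combined background fold (see [background_fold()]).
#' @return corrected L2.
#' @export
correct_l2 <- function(L2_apparent, fold) {
  check_positive(L2_apparent, "L2_apparent")
  check_positive(fold, "fold")
  L2_apparent / fold
}
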