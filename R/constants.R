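#' Physical and format design constants
#'
#' Fixed constants of the B-form DNA geometric model and of the design
#' procedure.  `rise_per_bp` (0.332 nm) reproduces the printed 42 bp =
#' 13.94 nm correspondence; `bp_per_turn` is the canonical 10.5 of B-form
#' DNA; `interhelix_spacing` separates the two antiparallel duplexes of a
#' DX edge; `ssdna_len_per_nt` is the contour length budgeted per unpaired
#' scaffold nucleotide when bridging vertex gaps.  `min_edge_bp_bound` and
#' `max_edge_bp_bound` bound the user-specifiable minimum edge length.
#'
#' @return A named list of constants (lengths in nm unless stated).
#' @export
#' @examples
#' dx_constants()$rise_per_bp
dx_constants <- function() {
  list(
    rise_per_bp       = 0.332,   # nm per base pair (B-form average rise)
    bp_per_turn       = 10.5,    # base pairs per helical turn
    duplex_diameter   = 2.0,     # nm, cylinder model diameter
    interhelix_spacing = 2.25,   # nm between the two duplex axes of an edge
    ssdna_len_per_nt  = 0.42,    # nm contour length per unpaired nucleotide
    min_edge_bp_bound = 42L,
    max_edge_bp_bound = 210L,
    m13_len           = 7249L,   # nt, M13mp18 scaffold length
    lambda_len        = 48502L   # nt, Lambda phage scaffold length
  )
}

# classed stop() so callers and tests can match error families
dx_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dxwire_error", "error",
                                     "condition")))
}

# run expr with a private RNG stream, restoring global .Random.seed
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
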