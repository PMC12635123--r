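`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement over the RNA alphabet (A<->U, C<->G); `N` maps to
#' itself. The result is reversed.
#'
#' @param x character vector of RNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp_rna <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so library calls do not perturb user code
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_usage <- function(...) stop(..., call. = FALSE)
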