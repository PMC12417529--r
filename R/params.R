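# Nested parameter containers. Trainable leaves are double arrays; integer
# leaves (geometry such as token counts, kernel sizes) and `spline_grid`
# objects are treated as fixed hyperparameters and skipped by param_map().

param_map <- function(p, fn) {
  if (inherits(p, "spline_grid")) return(p)
  if (is.list(p)) return(lapply(p, param_map, fn = fn))
  if (is.double(p)) return(fn(p))
  p
}

param_map2 <- function(a, b, fn) {
  if (inherits(a, "spline_grid")) return(a)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (nm in names(a)) out[[nm]] <- param_map2(a[[nm]], b[[nm]], fn)
    return(out)
  }
  if (is.double(a)) return(fn(a, b))
  a
}

param_wrap <- function(p) param_map(p, ad_leaf)

# pull accumulated gradients out of a wrapped (node) parameter tree
param_grads <- function(pn) {
  if (inherits(pn, "spline_grid")) return(pn)
  if (is_node(pn)) {
    g <- pn$grad
    if (is.null(g)) g <- if (is.null(dim(pn$val))) rep(0, length(pn$val)) else
      array(0, dim = dim(pn$val))
    return(g)
  }
  if (is.list(pn)) return(lapply(pn, param_grads))
  pn
}

param_count <- function(p) {
  n <- 0L
  walk <- function(q) {
    if (inherits(q, "spline_grid")) return(invisible(NULL))
    if (is.list(q)) { for (e in q) walk(e); return(invisible(NULL)) }
    if (is.double(q)) n <<- n + length(q)
    invisible(NULL)
  }
  walk(p)
  n
}
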