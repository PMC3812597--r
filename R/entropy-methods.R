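#' @describeIn complexityIndex sum a bare numeric vector of per-scale
#'   entropies; an empty vector is an error, `NA` scales make the result
#'   partial (attributes `partial`, `nDefined`).
#' @export
setMethod("complexityIndex", "numeric", function(x) {
  if (length(x) == 0L) stopf("empty entropy curve")
  ok <- !is.na(x)
  if (all(ok)) return(sum(x))
  structure(sum(x[ok]), partial = TRUE, nDefined = sum(ok))
})
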