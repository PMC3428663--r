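# internal helpers shared across modules

# promote a matrix or 3-d array to rows x cols x slices logical array
asMaskStack <- function(x, what = "mask") {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("%s must be a matrix or a 3-d array", what), call. = FALSE)
  if (is.logical(x)) {
    if (anyNA(x)) stop(sprintf("%s contains NA", what), call. = FALSE)
    return(x)
  }
  if (!is.numeric(x))
    stop(sprintf("%s must be logical or numeric", what), call. = FALSE)
  if (anyNA(x)) stop(sprintf("%s contains NA", what), call. = FALSE)
  if (any(x != 0 & x != 1))
    stop(sprintf("non-binary %s: values other than 0/1 present", what),
         call. = FALSE)
  array(x != 0, dim(x))
}

doeeCondition <- function(msg, class) {
  structure(class = c(class, "doeeError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

stopDoee <- function(msg, class) stop(doeeCondition(msg, class))

emptyRegionTable <- function() {
  data.frame(scan_id = character(), slice = integer(),
             label = character(), area_union = numeric(),
             area_r1 = numeric(), area_r2 = numeric(),
             area_intersection = numeric(), stringsAsFactors = FALSE)
}

checkRegionTable <- function(regions) {
  need <- c("scan_id", "slice", "label", "area_union", "area_r1",
            "area_r2", "area_intersection")
  if (!is.data.frame(regions) || !all(need %in% names(regions)))
    stop("'regions' must be a region table with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(regions$label), c("CR1", "CR2", "CR12"))
  if (length(bad))
    stop("unknown region labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(regions)
}
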