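# Embedding providers: the contract for turning feature/label names into
# descriptions and vectors, plus a deterministic offline provider so every
# downstream task is testable without network access. Adapters for hosted
# language-model APIs can implement the same contract as plug-ins; nothing in
# this package requires them.

#' Prompt template
#'
#' A template with exactly one `{}` placeholder where the feature or label
#' name is substituted before the text is sent to a description provider.
#'
#' @param template template string containing `{}` exactly once.
#' @param target_kind what the name denotes: `"gene"`, `"protein"` or
#'   `"cell_type"`.
#' @export
prompt_template <- function(template,
                            target_kind = c("gene", "protein", "cell_type")) {
  target_kind <- match.arg(target_kind)
  n_ph <- lengths(regmatches(template, gregexpr("\\{\\}", template)))
  assert_that(n_ph == 1L,
              "template must contain the placeholder {} exactly once (found ",
              n_ph, ")")
  structure(list(template = template, target_kind = target_kind),
            class = "PromptTemplate")
}

default_prompt_template <- function(target_kind = "gene") {
  tpl <- switch(target_kind,
    gene = "Describe the function of gene {} in a concise paragraph.",
    protein = "Describe the function of protein {} in a concise paragraph.",
    cell_type = "Describe the biological features of cell type {}.")
  prompt_template(tpl, target_kind)
}

#' Render a prompt for one name
#'
#' @param tpl PromptTemplate.
#' @param name nonempty feature or label name; passed through verbatim.
#' @return the prompt string.
#' @export
render_prompt <- function(tpl, name) {
  assert_that(inherits(tpl, "PromptTemplate"), "tpl must be a PromptTemplate")
  assert_that(is.character(name) && length(name) == 1L && nzchar(name),
              "name must be a nonempty string")
  sub("{}", name, tpl$template, fixed = TRUE)
}

#' Deterministic hash embedding of a string
#'
#' Maps a string to a unit-norm pseudo-random vector keyed by a stable string
#' hash, so identical inputs always give identical vectors and distinct
#' strings give near-orthogonal vectors for large `t`. This is the offline
#' embedding used by [hash_provider()].
#'
#' @param name_or_text string to embed.
#' @param t embedding dimension, `>= 1`.
#' @param seed integer seed mixed into the hash, so independent embedding
#'   tables can be generated from the same names.
#' @return numeric vector of length `t` with L2 norm 1.
#' @export
hash_embed <- function(name_or_text, t, seed = 0L) {
  assert_that(is.numeric(t) && length(t) == 1L && t >= 1,
              "t must be a positive integer")
  h <- string_hash32(paste0(name_or_text, "\x1f", seed))
  v <- with_seed(h %% 2147483647, stats::rnorm(as.integer(t)))
  v / sqrt(sum(v^2))
}

#' Offline deterministic embedding provider
#'
#' Implements the provider contract (`describe`: name -> text, `embed`:
#' text -> vector of `t` reals) with [render_prompt()] for descriptions and
#' [hash_embed()] for vectors.
#'
#' @param t embedding dimension.
#' @param seed integer seed.
#' @param template PromptTemplate; default a generic gene-function prompt.
#' @export
hash_provider <- function(t = 64L, seed = 0L,
                          template = default_prompt_template()) {
  assert_that(t >= 1, "t must be a positive integer")
  structure(list(
    describe = function(name) render_prompt(template, name),
    embed = function(text) hash_embed(text, t, seed),
    dim = as.integer(t)
  ), class = "EmbeddingProvider")
}

#' Build an embedding table for a list of names
#'
#' Renders a prompt per name, embeds it through the provider, and collects the
#' vectors into a [feature_embedding_table()]. Each distinct name is embedded
#' once (results are cached within the call).
#'
#' @param names unique character vector of feature or label names.
#' @param provider an `EmbeddingProvider` (see [hash_provider()]).
#' @param tpl optional PromptTemplate overriding the provider's description
#'   step.
#' @export
build_table <- function(names, provider, tpl = NULL) {
  assert_that(inherits(provider, "EmbeddingProvider"),
              "provider must be an EmbeddingProvider")
  assert_that(!anyDuplicated(names), "names must be unique")
  if (length(names) == 0L) {
    return(feature_embedding_table(character(),
                                   matrix(numeric(), 0, provider$dim)))
  }
  describe <- if (is.null(tpl)) provider$describe else {
    function(name) render_prompt(tpl, name)
  }
  cache <- new.env(parent = emptyenv())
  failed <- character(0)
  vecs <- matrix(NA_real_, length(names), provider$dim)
  for (i in seq_along(names)) {
    nm <- names[i]
    if (!is.null(cache[[nm]])) {
      vecs[i, ] <- cache[[nm]]
      next
    }
    v <- tryCatch(provider$embed(describe(nm)), error = function(e) NULL)
    if (is.null(v) || length(v) != provider$dim || !all(is.finite(v))) {
      failed <- c(failed, nm)
    } else {
      cache[[nm]] <- v
      vecs[i, ] <- v
    }
  }
  if (length(failed)) {
    stop_validation("provider failed for names: ",
                    paste(utils::head(failed, 20), collapse = ", "))
  }
  feature_embedding_table(names, vecs)
}
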