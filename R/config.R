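#' Default model and training configuration
#'
#' Returns the full set of tunable parameters with their defaults. Defaults
#' reflect the values selected for the pan-cancer analysis (embedding size
#' 512, attention size 256, 8 heads, dropout 0.2, Adam with learning rate
#' 1e-3 and weight decay 1e-5, batch size 100, early-stopping patience 30
#' evaluations with a 180-evaluation warm-up, at most 1000 iterations).
#' Any subset can be overridden via `...` or loaded from YAML with
#' [read_citrus_config()].
#'
#' @param ... named overrides of individual fields.
#' @return A named list of class `citrus_config`.
#' @examples
#' cfg <- citrus_config(embedding_dim = 64, attention_size = 32)
#' @export
citrus_config <- function(...) {
  cfg <- list(
    # architecture
    embedding_dim    = 512L,
    attention_size   = 256L,
    attention_heads  = 8L,
    dropout          = 0.2,
    max_alterations  = 1000L,
    activation       = "tanh",   # TF-layer activation: "tanh" or "relu"
    # initialization
    embedding_init_sd = 0.05,
    decoder_init_eps  = 0.01,
    # optimization
    learning_rate    = 1e-3,
    weight_decay     = 1e-5,
    batch_size       = 100L,
    patience         = 30L,
    warmup_eval_steps = 180L,
    max_iterations   = 1000L,
    eval_every       = 1L,       # epochs between validation evaluations
    seed             = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(
    cfg$embedding_dim >= 1, cfg$attention_size >= 1, cfg$attention_heads >= 1,
    cfg$dropout >= 0, cfg$dropout < 1,
    cfg$learning_rate > 0, cfg$weight_decay >= 0, cfg$batch_size >= 1,
    cfg$patience >= 1, cfg$warmup_eval_steps >= 0, cfg$max_iterations >= 1,
    cfg$activation %in% c("tanh", "relu")
  )
  structure(cfg, class = "citrus_config")
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path path to a YAML file with `citrus_config()` keys.
#' @return A `citrus_config` list.
#' @export
read_citrus_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(citrus_config, vals)
}
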