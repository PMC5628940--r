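# small worlds built in code for unit tests

open_grid <- function(w, h) {
  parse_grid_map(paste(rep(strrep(".", w), h), collapse = "\n"))
}

# 1 x n corridor with a start marker at the left and a reward site at the right
corridor_world <- function(n, reward = 0) {
  txt <- paste0("S", strrep(".", n - 2), "r")
  w <- parse_grid_map(txt)
  if (reward > 0) w <- set_reward(w, "R1", reward)
  w
}

expected_flexibility <- function() {
  matrix(c("fail", "fail", "fail",
           "pass", "fail", "fail",
           "pass", "pass", "fail",
           "pass", "pass", "pass",
           "pass", "fail", "fail",
           "pass", "pass", "pass",
           "fail", "fail", "fail"),
         nrow = 7, byrow = TRUE,
         dimnames = list(c("onestep_td", "sr_td", "sr_mb", "sr_dyna_k10000",
                           "sr_dyna_k10", "dyna_q_k10000", "dyna_q_k10"),
                         c("latent", "detour", "policy_reval")))
}
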