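# random admissible model states/environments under a fixed seed
random_state <- function() {
  los_state(AA = runif(1, 0, 80), HP = runif(1, 0, 20),
    HT = runif(1, 0, 5), LTA4 = runif(1, 0, 2), oxoETE = runif(1, 0, 50))
}
random_env <- function() {
  los_environment(PL = runif(1, 0, 150), Ca = runif(1, 0, 2000),
    GSH = runif(1, 0, 8000), GSSG = runif(1, 0, 4000),
    NADPH = runif(1, 0, 3000), NADP = runif(1, 0, 3000),
    LOOH = runif(1, 0, 100), LOH = runif(1, 0, 20),
    Z = runif(1, 0, 30), PF = runif(1, 0, 2),
    Fa = runif(1, 0.01, 1), GPx_full = runif(1, 0, 2e4),
    HEDH_full = runif(1, 0.01, 1), cpla2_scale = 10^runif(1, -4, 0))
}
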