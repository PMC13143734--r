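# Deviant-forager scenario: a scripted concealment, certain detection,
# a watcher who types the deviant, one declaration, one sanction.
world:
  n_agents: 4
  n_patches: 2
  patch_init: 10
  patch_cap: 10
  regen: 0.1
  y0: 1
  coop_c: 0.5
  n_signals: 2
  stranger_rate: 0.2
  gamma_att: 0
  p_detect: 1.0        # Pete's detection is certain here
  confiscate: true
  banish_ticks: 20
  alpha_increment: 0.1
  consensus_k: 1
  f_min: 3
  satiety_decay_every: 5
  satiety_max: 6
  encounter_rate: 1.0
  conceal_lookback: 10
agents:
  - id: adam
    controller: scripted
    group: band-A
    alpha: 0.5
  - id: eve
    controller: cooperator
    group: band-A
    alpha: 0.5
  - id: charles
    controller: V2
    group: band-B
    alpha: 0.5
    watch: true
  - id: pete
    controller: V2
    group: band-B
    alpha: 0.5
    watch: true
experiment:
  T: 15
  mode: sample
  theta: 0.5
  hysteresis: 0.1
  action_script:
    - {tick: 3, agent: adam, action: share}
    - {tick: 10, agent: adam, action: conceal}
  pairing_script:
    - {tick: 2, a: adam, b: pete}
    - {tick: 3, a: adam, b: pete}
    - {tick: 4, a: adam, b: pete}
    - {tick: 5, a: adam, b: pete}
    - {tick: 6, a: adam, b: pete}
    - {tick: 7, a: adam, b: pete}
    - {tick: 8, a: adam, b: pete}
    - {tick: 9, a: adam, b: pete}
    - {tick: 10, a: adam, b: pete}
    - {tick: 11, a: adam, b: pete}
    - {tick: 12, a: adam, b: pete}
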