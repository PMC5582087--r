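# Example run configuration for the swingboat pipeline runner.
# All keys have defaults; 'groups' drives simulation, 'monitors' (not shown)
# points at DAM monitor files on disk with channel->group assignments.
seed: 1
days: 20
lights_on: 8          # clock hour of lights-on (ZT0), LD12:12
bin_minutes: 1
sleep_threshold_min: 5
immobility_hours: 24
exercise:
  start_zt: 7
  duration_min: 30
  stimuli_per_minute: 3
  active_days: [1, 12]
groups:
  - profile: ad
    exercising: true
    n: 32
  - profile: ad
    exercising: false
    n: 32
  - profile: wild_type
    exercising: true
    n: 32
  - profile: wild_type
    exercising: false
    n: 32
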