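# Example generator configuration for the command-line front end:
#   Rscript inst/cli/dxrank.R generate --config generator-example.yaml \
#     --out corpus.jsonl --vocab-dir vocab/
# Field names mirror generator_config(); omitted fields keep their defaults.
n_diseases: 50
n_symptoms: 120
n_cases: 500
profile_size: [5, 9]
sensitivity: 0.8
noise_rate: 1.5
n_differentials: [4, 9]
confirmed_score: 17.0
decay: 0.7
profile_mode: random
seed: 7
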