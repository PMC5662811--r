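inducing perspiration
relieving superficies by cooling
opening the inhibited lung-energy
relieving asthma
clearing damp
subsidence of a swelling
cleaning heat
purging fire
cooling blood
detoxifying
dispelling wind
dispelling cold
dispelling dampness
warming the interior
regulating qi
promoting digestion
expelling parasites
stopping bleeding
activating blood circulation
removing blood stasis
resolving phlegm
stopping cough
calming the mind
soothing the liver
extinguishing wind
opening the orifices
tonifying qi
tonifying blood
tonifying yin
tonifying yang
astringing essence
relieving exterior syndrome
relieving uneasiness of mind
replenishing and restoring
dispelling internal cold
moistening dryness
promoting urination
relaxing the bowels
strengthening the spleen
harmonizing the stomach
nourishing the heart
benefiting the kidneys
clearing the head and eyes
relieving pain
regulating menstruation
promoting lactation
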