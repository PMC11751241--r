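species,origin,mean_mass_kg,provenance
blue_sheep,wild,55,synthetic plausible value; edit before real use
dog,domestic,20,synthetic plausible value; edit before real use
domestic_goat,domestic,35,synthetic plausible value; edit before real use
domestic_sheep,domestic,30,synthetic plausible value; edit before real use
himalayan_marmot,wild,5,synthetic plausible value; edit before real use
horse,domestic,250,synthetic plausible value; edit before real use
least_weasel,wild,0.1,synthetic plausible value; edit before real use
mountain_weasel,wild,0.25,synthetic plausible value; edit before real use
pika,wild,0.15,synthetic plausible value; edit before real use
stone_marten,wild,1.5,synthetic plausible value; edit before real use
yak,domestic,300,synthetic plausible value; edit before real use
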