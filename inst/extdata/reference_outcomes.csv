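name,temperature,termini,verdict,key_event,footnotes
5N2D,300,charged,unstable,collapse,
6N2D,300,charged,unstable,dissociation,
7N2D,300,charged,unstable,dissociation,
8N2D,300,charged,unstable,dissociation,
5N2S,300,charged,unstable,disintegration,
6N2S,300,charged,unstable,dissociation,
7N2S,300,charged,unstable,dissociation,
8N2S,300,charged,unstable,disintegration,
5N6D,300,charged,unstable,dissociation,
6N6D,300,charged,unstable,disintegration,
7N6D,300,charged,unstable,disintegration,
8N6D,300,charged,unstable,disintegration,
5N2D*,300,neutral,unstable,dissociation,
6N2D*,300,neutral,stable,none,"extended,reinitiated"
7N2D*,300,neutral,stable,none,
8N2D*,300,neutral,unstable,dissociation,
5N2S*,300,neutral,stable,none,
6N2S*,300,neutral,stable,none,
7N2S*,300,neutral,stable,none,
8N2S*,300,neutral,stable,none,extended
5N6D*,300,neutral,stable,none,extended
6N6D*,300,neutral,stable,none,
7N6D*,300,neutral,stable,none,
8N6D*,300,neutral,stable,none,
5N2D,330,charged,unstable,disintegration,
6N2D,330,charged,unstable,dissociation,
7N2D,330,charged,unstable,disintegration,
8N2D,330,charged,unstable,dissociation,
5N2S,330,charged,unstable,dissociation,
6N2S,330,charged,unstable,disintegration,
7N2S,330,charged,unstable,disintegration,
8N2S,330,charged,unstable,disintegration,
5N6D,330,charged,unstable,dissociation,
6N6D,330,charged,unstable,disintegration,
7N6D,330,charged,unstable,disintegration,
8N6D,330,charged,unstable,disintegration,
5N2D*,330,neutral,unstable,disorder,
6N2D*,330,neutral,unstable,dissociation,
7N2D*,330,neutral,unstable,dissociation,
8N2D*,330,neutral,unstable,dissociation,
5N2S*,330,neutral,stable,dissociation,"extended,late_instability"
6N2S*,330,neutral,stable,none,
7N2S*,330,neutral,stable,none,"extended,reinitiated"
8N2S*,330,neutral,stable,none,
5N6D*,330,neutral,unstable,rearrangement,
6N6D*,330,neutral,unstable,disintegration,
7N6D*,330,neutral,stable,none,extended
8N6D*,330,neutral,unstable,dissociation,
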