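raw_term	canonical_pattern	category
essence	essence	essential components
qi	qi	essential components
spirit	spirit	essential components
blood	blood	essential components
phlegm	phlegm	essential components
liver	liver	viscera and bowels
heart	heart	viscera and bowels
pericardium	pericardium	viscera and bowels
spleen	spleen	viscera and bowels
lung	lung	viscera and bowels
kidney	kidney	viscera and bowels
gallbladder	gallbladder	viscera and bowels
stomach	stomach	viscera and bowels
small intestine	small intestine	viscera and bowels
large intestine	large intestine	viscera and bowels
bladder	bladder	viscera and bowels
triple energizers	triple energizers	viscera and bowels
food	food	internal/external causes
overwork	overwork	internal/external causes
sexual activity	sexual activity	internal/external causes
wind	wind	internal/external causes
cold	cold	internal/external causes
dampness	dampness	internal/external causes
dryness	dryness	internal/external causes
fire	fire	internal/external causes
sovereign fire	fire	internal/external causes
ministerial fire	fire	internal/external causes
heat	fire	internal/external causes
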