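%
01	HarmVirtue
02	HarmVice
03	FairnessVirtue
04	FairnessVice
05	IngroupVirtue
06	IngroupVice
07	AuthorityVirtue
08	AuthorityVice
09	PurityVirtue
10	PurityVice
11	MoralityGeneral
%
care	01
caring	01
kind*	01
protect*	01
safe*	01
kill*	02
harm*	02
cruel*	02
war	02
fair	03
fairness	03
justice	03
equal*	03
honest*	03
cheat*	04
unfair*	04
dishonest*	04
loyal*	05
family	05
patriot*	05
together	05
betray*	06
traitor*	06
foreign*	06
obey*	07
duty	07
respect*	07
law	07
rebel*	08
defian*	08
riot*	08
pure	09
sacred*	09
clean*	09
holy	09
filth*	10
disgust*	10
impur*	10
sin	10
moral*	11
immoral*	11
ethic*	11
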