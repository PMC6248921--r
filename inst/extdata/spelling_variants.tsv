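centre	center
centres	centers
colour	color
colours	colors
favour	favor
favours	favors
favourite	favorite
favourites	favorites
behaviour	behavior
behaviours	behaviors
neighbour	neighbor
neighbours	neighbors
neighbourhood	neighborhood
honour	honor
honours	honors
labour	labor
flavour	flavor
flavours	flavors
humour	humor
rumour	rumor
rumours	rumors
theatre	theater
theatres	theaters
metre	meter
metres	meters
litre	liter
litres	liters
fibre	fiber
travelling	traveling
travelled	traveled
traveller	traveler
cancelled	canceled
modelling	modeling
jewellery	jewelry
grey	gray
defence	defense
offence	offense
licence	license
practise	practice
organise	organize
organised	organized
realise	realize
realised	realized
recognise	recognize
apologise	apologize
analyse	analyze
cheque	check
programme	program
catalogue	catalog
dialogue	dialog
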